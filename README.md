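# phceff

Allocation and spatial efficiency analysis for primary-health-care (PHC)
systems: does putting more resources into a region's primary care make the
system run more efficiently, and does good allocation spill over onto
neighbouring regions?

`phceff` is aimed at health-services researchers working with regional
panels (e.g. 31 provinces x 5 years) of resource indicators, service
volumes and covariates. It implements the full chain used in
province-level PHC efficiency studies:

| Stage | Method | Function |
|---|---|---|
| Resource allocation index | Entropy weight method; CHRDI = u / sqrt(pop x area) | `entropy_weights()`, `chrdi_series()` |
| Technical efficiency | Input-oriented DEA (CRS/VRS), min θ s.t. θx_i − X'λ ≥ 0, Y'λ ≥ y_i | `dea_te()` |
| Bias correction | Simar–Wilson homogeneous smoothed bootstrap (reflection, Silverman bandwidth, B = 2000) | `simar_wilson()`, `efficiency_panel()` |
| Allocation vs efficiency | Mean-centred quadrant classification (I high/high … IV high/low) | `quadrant_classify()` |
| Spatial dependence | Global/local Moran's I, E(I) = −1/(N−1), randomization/permutation inference, HH/HL/LL/LH clusters | `global_moran()`, `moran_test()`, `local_moran()` |
| Spillovers | ML fixed-effects spatial Durbin model Y = ρWY + Xβ + WXθ + μ + ε with direct/indirect/total impacts S_k(W) = (I−ρW)⁻¹(Iβ_k + Wθ_k) | `fit_sdm()`, `sdm_impacts()`, `lr_test()`, `hausman_test()`, `vif()` |

Spatial weights are built from coordinates (`inverse_distance_weights()`,
great-circle or planar) or supplied as matrices (`spatial_weights()`);
synthetic generators (`simulate_dea_panel()`, `simulate_sdm_panel()`,
`simulate_indicator_panel()`, `make_coordinates()`) state a fully known
world for every stage, and `run_pipeline()` orchestrates everything from
two CSVs to a bundle of output tables. Reference tables transcribed from a
published 31-province analysis ship as plain-CSV fixtures
(`load_fixture()`).

The DEA envelopment LPs are solved by a compiled two-phase simplex
(RcppArmadillo) written for this package; B = 2000 bootstrap replicates at
N = 31 take a few seconds.

## Worked example

```r
library(phceff)

## 1. allocation vs efficiency quadrants on the packaged reference tables
t2 <- load_fixture("table2_chrdi")
t4 <- load_fixture("table4_efficiency")
ch <- with(t2[t2$year == 2016, ], setNames(chrdi, unit_id))
ef <- with(t4[t4$year == 2016, ], setNames(corrected, unit_id))
table(quadrant_classify(ch, ef))
#>   I  II III  IV
#>  12  11   8   0
```

12 + 8 = 20 provinces sit in quadrants I and III in 2016: high allocation
tends to go with high bias-corrected efficiency (and low with low).

```r
## 2. bias-corrected DEA on a synthetic production panel with known truth
sim <- simulate_dea_panel(n_units = 31, n_years = 1, sigma_u = 0.3, seed = 1)
sw  <- simar_wilson(sim$instances[[1]], rts = "vrs", B = 2000, seed = 2)
head(round(sw[, -1], 3), 4)
#>   theta theta_bc  bias ci_low ci_high
#> 1 1.000    0.932 0.068  0.749   0.998
#> 2 0.853    0.832 0.022  0.794   0.852
#> 3 1.000    0.938 0.062  0.834   0.998
#> 4 1.000    0.923 0.077  0.638   0.998
```

Frontier scores of exactly 1 are optimistic; the bootstrap estimates the
upward bias and subtracts it (`theta_bc < theta`, always).

```r
## 3. spatial Durbin model with impact decomposition on a known world
co <- make_coordinates(31, "grid")
W  <- grid_contiguity_weights(co, "row")
panel <- simulate_sdm_panel(W, n_years = 5, rho = 0.4, beta = c(1, -0.5),
                            theta = c(0.8, 0), seed = 3)
fit <- fit_sdm(panel$data, "y", c("x1", "x2"), W)
fit
#> SDM fit ( unit effects ): N = 31 T = 5
#> rho = 0.5105  sigma2 = 0.2825  loglik = -103.178
#>          x1          x2        W.x1        W.x2
#>  1.02128157 -0.55867515  0.58750050  0.05889547

round(sdm_impacts(fit, nsim = 500, seed = 4)[, 1:3], 3)
#>    direct indirect  total
#> x1  1.238    2.049  3.287
#> x2 -0.603   -0.418 -1.021
```

The direct effect of `x1` is its own-region impact (feedback included);
the indirect effect is the spillover accumulated over neighbours through
(I − ρW)⁻¹; total = direct + indirect (an exact identity). Single-draw
estimates scatter around the truth — across 200 replicates the mean of
rho-hat is within 0.01 of 0.4 (see the acceptance report).

## Layout

* `R/`, `src/` — implementation (entropy/CHRDI, DEA + bootstrap + simplex,
  Moran, SDM, generators, pipeline)
* `inst/extdata/` — transcribed reference tables (CSV)
* `inst/cli/phceff.R` — command-line entry point (`run`, `simulate`,
  `fixtures`)
* `vignettes/allocation-efficiency.Rmd` — methods, design decisions and
  limitations
* `tests/testthat/` — unit, property and acceptance suites
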