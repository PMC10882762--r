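---
title: "Resource allocation and spatial efficiency of primary health care:
  methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource allocation and spatial efficiency: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phceff)
```

## The problem

Health planners want to know whether the resources put into
primary-health-care (PHC) systems — institutions, beds, staff, subsidies —
are allocated where they produce services efficiently, and whether a
region's allocation spills over onto its neighbours. `phceff` implements a
complete analysis chain for province-level (or any regional) panels:

1. **Entropy-weighted composite resource index** and a **comprehensive
   health resource density index (CHRDI)** that balances population and
   geographic density;
2. **Input-oriented DEA** technical efficiency with **Simar–Wilson
   smoothed-bootstrap bias correction**;
3. **Quadrant classification** crossing allocation against efficiency;
4. **Global and local Moran's I** for spatial dependence of efficiency;
5. A **fixed-effects spatial Durbin model (SDM)** with direct / indirect /
   total impact decomposition.

Each stage is exercised end-to-end on synthetic panels with known truth,
plus packaged reference tables transcribed from a published 31-province,
2016–2020 analysis (`load_fixture()`).

## Entropy weights and CHRDI

For each year (or the pooled panel), indicator $j$ over $m$ units is
min–max standardized with orientation: positive indicators map to
$(x-\min)/(\max-\min)$, negative to $(\max-x)/(\max-\min)$. With shares
$P_{ij} = X'_{ij} / \sum_i X'_{ij}$, the Shannon entropy
$e_j = -\tfrac{1}{\ln m}\sum_i P_{ij}\ln P_{ij}$ (with $0\ln 0 := 0$),
difference coefficient $g_j = 1 - e_j$ and weights
$W_j = g_j / \sum_j g_j$. Dispersed indicators (low entropy) are more
informative and get more weight. The composite index is
$u_i = \sum_j W_j X'_{ij} \in [0,1]$ and

$$\mathrm{CHRDI}_i \;=\;
\sqrt{\frac{u_i}{\text{population (thousands)}}\times
      \frac{u_i}{\text{area (km}^2)}}
\;=\; \frac{u_i}{\sqrt{\text{pop}\cdot\text{area}}}.$$

Design notes:

* **Parenthesization.** Some applied write-ups print the standardization
  without parentheses; only the $(x-\min)/(\max-\min)$ reading keeps values
  in $[0,1]$, so that is what is implemented.
* **$0\ln 0$.** The limit convention is the default; a `zero_shift`
  option adds a small constant to all entries first, because part of the
  applied literature does that and it changes weights slightly.
* **Per-year vs pooled standardization** (`mode` in `chrdi_series()`).
  Per-year weighting is the default: it matches the observation that
  entropy weights barely move between years, which only makes sense if they
  were computed per year. But note a consequence verified by the synthetic
  generator: per-year min–max standardization removes any level shift
  common to all units, so a shared growth trend in raw resources leaves the
  per-year composite index flat. Reference CHRDI series that rise over time
  for nearly every unit are therefore consistent with *pooled*
  standardization; the trend test in the suite uses `mode = "pooled"` for
  exactly this reason. Both modes are first-class.
* No deflation of financial indicators is applied.

## DEA and the Simar–Wilson bootstrap

Technical efficiency of unit $i$ is the radial input contraction
$\theta_i$ solving

$$\min\theta \quad \text{s.t.} \quad \theta x_i - X'\lambda \ge 0,\;
Y'\lambda \ge y_i,\; \lambda \ge 0$$

with $\sum\lambda = 1$ added under variable returns to scale (VRS).
$\theta = 1$ is the empirical frontier. The LPs are solved by a dense
two-phase simplex written for this package (no LP solver is available in
the target environment); it is validated against the closed-form
ratio-to-best oracle for single-input single-output CRS instances and
against radial-measure invariances (units invariance, dominated-DMU
irrelevance, VRS $\ge$ CRS nesting).

Because the frontier is estimated from the same data, $\hat\theta$ is
biased towards 1. `simar_wilson()` implements the homogeneous smoothed
bootstrap: reflect $\{\hat\theta\}$ about 1, pick a Gaussian-kernel
bandwidth by Silverman's rule on the reflected sample, draw with
replacement plus kernel noise, shrink by the variance-correction factor
$1/\sqrt{1+h^2/\hat\sigma^2}$, fold back into $(0,1]$, rescale inputs into
pseudo-data $x^*_j = (\hat\theta_j/\theta^*_j)x_j$, re-solve each original
DMU against the pseudo-frontier, and subtract the estimated bias
$\overline{\hat\theta^*_b} - \hat\theta$. Percentile intervals come from
$\{2\hat\theta - \hat\theta^*_b\}$.

Design notes:

* **Returns to scale.** Both the traditional scores and the bootstrap run
  under VRS by default (`rts = "crs"` available): the homogeneous bootstrap
  is standard under VRS, and VRS is the operative choice for a
  heterogeneous set of provinces.
* $B = 2000$ replicates by default; B = 2000 at $N = 31$ takes a few
  seconds with the compiled solver.
* Degenerate case: if every DMU sits on the frontier there is no variation
  to smooth and the function refuses to run rather than fabricate a bias.

## Quadrants

`quadrant_classify()` crosses CHRDI against (bias-corrected) efficiency
with both axes centred at their cross-unit means: quadrant I = high/high,
II = low/high, III = low/low, IV = high/low. Values exactly at the mean
count as "low", which makes the all-identical edge case deterministic
(everything in III). On the packaged 2016 reference tables this reproduces
the published count of 20 provinces in quadrants I + III.

## Moran's I

Global: $I = \frac{\sum_{ij} w_{ij} (x_i-\bar x)(x_j-\bar x)}
{\frac1N \sum_i (x_i-\bar x)^2 \cdot \sum_{ij} w_{ij}}$, with null
expectation $-1/(N-1)$ ($-0.033$ at $N = 31$). Local:
$I_i = N (x_i-\bar x) \sum_j w_{ij}(x_j-\bar x) / \sum_i (x_i-\bar x)^2$,
with the identity $\sum_i I_i = I \cdot \sum_{ij} w_{ij}$ tested to 1e-9.
Cluster labels follow the sign pattern of own deviation and spatial lag
(HH, HL, LL, LH), reported only when significant.

Design notes:

* **Variance.** The closed-form "randomization" (kurtosis-adjusted)
  variance is the default because published tables print a z column
  without naming an assumption; `"normality"` and `"permutation"` are
  available, and permutation is the robust choice for small N.
* **Sidedness.** One-sided (greater) for the global test, matching the
  positive-dependence claims such analyses make; two-sided conditional
  permutation (999 draws) for local statistics, with a one-sided option.
* No multiple-testing correction on local p-values by default, mirroring
  the per-unit $\alpha = 0.05$ filter such tables use.
* **Weights.** `inverse_distance_weights()` builds $w_{ij} = 1/d_{ij}$
  (great-circle km on a 6371-km sphere for lat/lon; Euclidean for planar),
  row-standardized or raw. Which point represents a region and whether the
  matrix was row-standardized are surfaced as explicit configuration — the
  reference tables do not pin them down, so their I/sd/z values are not
  used as solver oracles (only $E(I)$ is).

## The spatial Durbin model

$$Y = \rho W Y + X\beta + W X \theta + \mu + \varepsilon$$

estimated by concentrated maximum likelihood on the within-transformed
panel: for each candidate $\rho$, slopes come from least squares of
$y^* - \rho (Wy)^*$ on $[X^*, (WX)^*]$, and $\log|I_N - \rho W|$ is
evaluated from the eigenvalues of $W$ (computed once; exact at $N = 31$).
`sdm_impacts()` decomposes marginal effects through
$S_k(W) = (I-\rho W)^{-1}(I\beta_k + W\theta_k)$: direct = mean diagonal,
total = mean row sum, indirect = difference, with simulation-based
standard errors. `lr_test()` compares the SDM against its spatial-lag
($\theta = 0$) and spatial-error (common-factor) restrictions;
`hausman_test()` screens fixed vs random effects on the non-spatial
within model; `vif()` covers the collinearity table.

Design notes:

* **Static, not dynamic.** The model has no time-lagged dependent term:
  the printed equation in the source analysis is static and its $N = 155$
  matches a 31 x 5 static panel.
* **Effective-sample likelihood.** The within transformation removes one
  observation per unit worth of information. The likelihood therefore uses
  the orthonormal-transformation convention for short panels: effective
  sample $N(T-1)$ under unit effects and log-det multiplier $T-1$
  (analogously for time and two-way effects). Without this, the LR test of
  SDM vs SLM over-rejects badly at $T = 5$ (11.5% at nominal 5% in our
  calibration; 6% with the convention), and $\sigma^2$ is biased low. This
  is the standard remedy for short fixed-effects spatial panels.
* **Weight-matrix identification.** A dense row-standardized
  inverse-distance matrix identifies $\rho$ only weakly at $N = 31$: in
  simulation the ML estimate has sd $\approx 0.22$ and a persistent
  downward bias even with no fixed effects, purely because all rows of
  $W$ are nearly proportional. A sparse lattice (rook-contiguity) matrix
  recovers $\rho = 0.4$ to within 0.01 on average. The parameter-recovery
  suite therefore runs on the lattice (`grid_contiguity_weights()`), while
  real-data runs may still use inverse distance — with the caveat above.
* **$R^2$.** Both a within-$R^2$ and a squared-correlation variant are
  reported; anomalously low published values of this statistic are not
  used as targets because their definition is not recoverable.
* Significance levels for stars follow the 90/95/99% convention.

## The synthetic world

The generators state the world the tests assume; their defaults are fixed
and are not tuned against test outcomes.

* `simulate_dea_panel()`: log-normal inputs, Cobb–Douglas frontier
  ($\sum a_j \le 1$), half-normal inefficiency $u$ with $\sigma_u = 0.3$,
  **no two-sided noise by default** (DEA assumes an error-free frontier;
  `sigma_v > 0` exists to demonstrate what noise does and is clearly
  off-model). True input efficiency $e^{-u/\sum a_j}$ is recorded for
  recovery tests.
* `simulate_sdm_panel()`: the SDM reduced form
  $Y = (I-\rho W)^{-1}(X\beta + WX\theta + \mu + \varepsilon)$ with
  defaults $N = 31$, $T = 5$, $\rho = 0.4$, $\beta = (1, -0.5)$,
  $\theta = (0.8, 0)$, $\sigma = 0.5$, matching the panel geometry the
  reference analysis uses. The truth record carries every draw, so the
  reduced form is re-verifiable to 1e-10.
* `simulate_indicator_panel()`: log-normal indicator levels with
  persistent unit size factors and a common upward trend; population and
  area fixed over years.

What a green test establishes: the estimators recover the parameters of
*this* world (correct formulas, correct code paths, calibrated inference).
What it does not: that real yearbook data satisfy the world's assumptions
— no measurement error in DEA inputs, Gaussian SDM errors, correctly
specified $W$. The packaged reference tables bridge part of that gap
(classification and arithmetic checks), but the raw microdata behind them
are not public, so absolute efficiency magnitudes and SDM coefficient
values are out of reach by design.

## Numerical choices

* LP solver: dense two-phase simplex, Dantzig pricing with Bland's rule
  after half the iteration budget (envelopment LPs are heavily
  degenerate); pivot tolerance 1e-9; self-evaluation scores clipped to
  $(10^{-9}, 1]$.
* $\rho$ search: golden-section/parabolic (`optimize`) over the interval
  defined by the extreme real eigenvalues of $W$, tolerance 1e-10;
  boundary estimates trigger a warning.
* Variance of $(\hat\delta, \hat\rho)$: numerical Hessian of the full
  transformed likelihood in $(\delta, \rho, \log\sigma^2)$; a pseudo-
  inverse fallback handles near-singular cases (flagged in the Hausman
  screen).
* Ties at the quadrant mean go to "low"; cluster labels with zero lag go
  to the negative-lag side; both rules are degenerate-input conventions,
  not substantive claims.
* Every stochastic routine takes an explicit `seed`; the pipeline derives
  per-stage seeds from one global seed by fixed offsets, so single stages
  re-run bit-identically from cached CSVs.

## Known limitations

* No Malmquist productivity decomposition, super-efficiency, slack-based
  measures, or pure-technical/scale split.
* No Geary's C or Getis–Ord statistics; no choropleth rendering.
* No Bayesian/GMM spatial estimators and no random-effects SDM beyond the
  Hausman screen; no time-lagged (dynamic) SDM.
* Contiguity matrices for real geographies must be supplied by the user;
  the package only builds inverse-distance matrices from coordinates and
  rook lattices for synthetic grids.
* One packaged reference table's bottom summary row is arithmetically
  inconsistent with its own printed cells; the suite recomputes the
  faithful values and documents the discrepancy rather than matching the
  printed row.
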