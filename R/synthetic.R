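# Synthetic-data generators emulating the statistical structure each stage
# assumes: a Cobb-Douglas production panel with known inefficiency, a
# log-normal resource-indicator panel with a common upward trend, and a
# spatial Durbin panel generated from its reduced form with known
# parameters. Defaults mirror a 31-unit x 5-year province panel.

#' Synthetic unit coordinates
#'
#' @param n number of units (>= 4).
#' @param layout `"grid"` (fill the smallest square lattice with >= n cells,
#'   unit spacing) or `"random"` (uniform on a 10 x 10 square).
#' @param seed optional seed (random layout).
#' @return `coordinate_table` with planar x, y.
#' @export
make_coordinates <- function(n, layout = c("grid", "random"), seed = NULL) {
  layout <- match.arg(layout)
  if (n < 4) stop("need at least 4 units")
  if (!is.null(seed)) set.seed(seed)
  if (layout == "grid") {
    side <- ceiling(sqrt(n))
    g <- expand.grid(x = seq_len(side), y = seq_len(side))[seq_len(n), ]
    df <- data.frame(unit_id = sprintf("u%02d", seq_len(n)),
                     x = as.numeric(g$x), y = as.numeric(g$y))
  } else {
    repeat {
      xy <- matrix(runif(2 * n, 0, 10), n, 2)
      if (min(dist(xy)) > 1e-3) break
    }
    df <- data.frame(unit_id = sprintf("u%02d", seq_len(n)),
                     x = xy[, 1], y = xy[, 2])
  }
  coordinate_table(df, planar = TRUE)
}

#' Simulate a multi-input multi-output production panel for DEA
#'
#' Inputs are log-normal; the frontier is Cobb-Douglas,
#' `g(x) = prod_j x_j^(a_j)` with `sum(a_j) = 1` under CRS and `< 1` under
#' VRS; observed output is `y = g(x) * exp(-u)` with half-normal
#' inefficiency `u ~ |N(0, sigma_u^2)|` and no two-sided noise by default
#' (DEA assumes an error-free frontier). The recorded true input-oriented
#' efficiency is `exp(-u / sum(a_j))`. An optional two-sided log-normal
#' measurement error (`sigma_v > 0`) is available to demonstrate DEA's
#' sensitivity to noise; it is off-model for DEA and off by default.
#'
#' @param n_units,n_years panel dimensions.
#' @param exponents Cobb-Douglas exponents (one per input).
#' @param n_outputs number of outputs; the frontier output is split across
#'   outputs with fixed positive shares.
#' @param sigma_u half-normal inefficiency scale.
#' @param sigma_v two-sided log-noise scale (default 0).
#' @param trend multiplicative yearly frontier-productivity growth (e.g.
#'   -0.02 shrinks the frontier 2\% a year).
#' @param seed optional seed.
#' @return list with `instances` (one `dea_instance` per year, named by
#'   year), `truth` (data.frame unit, year, u, theta_true) and the
#'   generating parameters.
#' @export
simulate_dea_panel <- function(n_units = 31, n_years = 5,
                               exponents = c(0.25, 0.2, 0.2, 0.15),
                               n_outputs = 3, sigma_u = 0.3, sigma_v = 0,
                               trend = 0, seed = NULL) {
  if (any(exponents <= 0)) stop("exponents must be positive")
  if (sum(exponents) > 1 + 1e-12)
    stop("sum of exponents must be <= 1 (VRS) or == 1 (CRS)")
  if (!is.null(seed)) set.seed(seed)
  p <- length(exponents)
  shares <- (seq_len(n_outputs) + 1) / sum(seq_len(n_outputs) + 1)
  units <- sprintf("u%02d", seq_len(n_units))
  years <- 2000L + seq_len(n_years)
  instances <- list()
  truth <- NULL
  for (s in seq_len(n_years)) {
    X <- matrix(rlnorm(n_units * p, meanlog = 1, sdlog = 0.4), n_units, p)
    u <- abs(rnorm(n_units, 0, sigma_u))
    g <- (1 + trend)^(s - 1) *
      exp(rowSums(sweep(log(X), 2, exponents, "*")))
    ytot <- g * exp(-u)
    if (sigma_v > 0) ytot <- ytot * exp(rnorm(n_units, 0, sigma_v))
    Y <- outer(ytot, shares)
    instances[[as.character(years[s])]] <-
      dea_instance(X, Y, labels = units)
    truth <- rbind(truth,
                   data.frame(unit_id = units, year = years[s], u = u,
                              theta_true = exp(-u / sum(exponents))))
  }
  list(instances = instances, truth = truth,
       params = list(exponents = exponents, sigma_u = sigma_u,
                     sigma_v = sigma_v, trend = trend, seed = seed))
}

#' Simulate a spatial Durbin panel from its reduced form
#'
#' Generates `Y = (I - rho*W)^{-1} (X*beta + W*X*theta + mu + eps)` year by
#' year with unit effects `mu ~ N(0, sigma_mu^2)` (optionally correlated
#' with the first regressor's unit mean, to exercise the Hausman screen)
#' and noise `eps ~ N(0, sigma^2)`.
#'
#' @param W `spatial_weights` (row-standardized) or matrix; defines N.
#' @param n_years number of years.
#' @param rho spatial autoregressive parameter (inside W's interval).
#' @param beta,theta regressor and spatial-lag coefficient vectors (equal
#'   length; k regressors named x1..xk).
#' @param sigma noise sd; `sigma_mu` unit-effect sd.
#' @param x_corr pairwise correlation between regressors.
#' @param mu_x_corr correlation between the unit effect and unit-level mean
#'   of x1 (0 = RE-consistent world).
#' @param seed optional seed.
#' @return list with `data` (long data.frame unit_id, year, y, x1..xk) and
#'   `truth` (all generating draws: mu, eps, X, plus the parameters), so
#'   the reduced form can be re-verified exactly.
#' @export
simulate_sdm_panel <- function(W, n_years = 5, rho = 0.4,
                               beta = c(1, -0.5), theta = c(0.8, 0),
                               sigma = 0.5, sigma_mu = 0.5, x_corr = 0.3,
                               mu_x_corr = 0, seed = NULL) {
  Wm <- as_weights_matrix(W)
  ids <- if (inherits(W, "spatial_weights")) W$ids else
    rownames(Wm) %||% sprintf("u%02d", seq_len(nrow(Wm)))
  n <- nrow(Wm)
  k <- length(beta)
  if (length(theta) != k) stop("beta and theta must have equal length")
  iv <- rho_interval(Wm)
  if (rho <= iv[1] || rho >= iv[2])
    stop("rho outside the invertibility interval (",
         format(iv[1]), ", ", format(iv[2]), ")")
  if (!is.null(seed)) set.seed(seed)
  A <- solve(diag(n) - rho * Wm)
  # regressors with exchangeable cross-correlation x_corr
  C <- matrix(x_corr, k, k); diag(C) <- 1
  L <- chol(C)
  mu <- rnorm(n, 0, sigma_mu)
  years <- 2000L + seq_len(n_years)
  Xl <- lapply(seq_len(n_years), function(s)
    matrix(rnorm(n * k), n, k) %*% L)
  if (mu_x_corr != 0) {
    x1bar <- rowMeans(vapply(Xl, function(M) M[, 1], numeric(n)))
    x1s <- (x1bar - mean(x1bar)) / sd(x1bar)
    mu <- sigma_mu * (mu_x_corr * x1s +
                        sqrt(1 - mu_x_corr^2) * rnorm(n))
  }
  rows <- list()
  eps_rec <- list()
  for (s in seq_len(n_years)) {
    X <- Xl[[s]]
    eps <- rnorm(n, 0, sigma)
    eps_rec[[s]] <- eps
    y <- drop(A %*% (X %*% beta + Wm %*% X %*% theta + mu + eps))
    d <- data.frame(unit_id = ids, year = years[s], y = y)
    for (j in seq_len(k)) d[[paste0("x", j)]] <- X[, j]
    rows[[s]] <- d
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data,
       truth = list(rho = rho, beta = beta, theta = theta, sigma = sigma,
                    sigma_mu = sigma_mu, mu = setNames(mu, ids),
                    eps = eps_rec, X = Xl, years = years, seed = seed))
}

#' Simulate a resource-indicator panel
#'
#' Indicator levels are log-normal with unit-specific size factors and a
#' common upward year trend; population (thousands) and area (km2) are
#' fixed over years. Mirrors the structure of a province resource table:
#' four positively oriented resource indicators plus denominators.
#'
#' @param n_units,n_years panel dimensions.
#' @param indicators names of the resource indicators.
#' @param trend common log-linear yearly growth of indicator levels.
#' @param sigma log-scale noise sd of indicator levels (0 with identical
#'   units produces degenerate columns downstream, by design).
#' @param seed optional seed.
#' @return an `indicator_panel` containing the resource indicators plus
#'   `population` and `area`.
#' @export
simulate_indicator_panel <- function(n_units = 31, n_years = 5,
                                     indicators = c("institutions",
                                                    "health_technicians",
                                                    "beds", "subsidies"),
                                     trend = 0.05, sigma = 0.3,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- sprintf("u%02d", seq_len(n_units))
  years <- 2000L + seq_len(n_years)
  size <- rlnorm(n_units, 0, 0.8)               # persistent unit size
  pop <- size * rlnorm(n_units, log(5000), 0.4) # thousands
  area <- rlnorm(n_units, log(150000), 0.9)     # km2
  rows <- list()
  for (s in seq_len(n_years)) {
    for (ind in indicators) {
      lev <- size * exp(trend * (s - 1)) * rlnorm(n_units, 2, sigma)
      rows[[length(rows) + 1]] <-
        data.frame(unit_id = units, year = years[s], indicator = ind,
                   value = lev)
    }
    rows[[length(rows) + 1]] <-
      data.frame(unit_id = units, year = years[s], indicator = "population",
                 value = pop)
    rows[[length(rows) + 1]] <-
      data.frame(unit_id = units, year = years[s], indicator = "area",
                 value = area)
  }
  indicator_panel(do.call(rbind, rows))
}

#' Rook-contiguity weights for synthetic lattice coordinates
#'
#' Binary rook adjacency (unit grid spacing) for coordinates produced by
#' [make_coordinates()] with the grid layout. Sparse lattice weights
#' identify the spatial autoregressive parameter much more strongly than
#' dense inverse-distance weights in small panels, so the parameter-recovery
#' experiments use them. Real-data contiguity matrices must be supplied by
#' the user; this helper is for synthetic lattices only.
#'
#' @param coords planar `coordinate_table` on an integer grid.
#' @param standardization `"row"` (default) or `"none"`.
#' @return `spatial_weights` of kind `"binary_contiguity"`.
#' @export
grid_contiguity_weights <- function(coords,
                                    standardization = c("row", "none")) {
  standardization <- match.arg(standardization)
  if (!isTRUE(attr(coords, "planar")))
    stop("grid contiguity requires planar grid coordinates")
  xy <- cbind(coords$x, coords$y)
  n <- nrow(xy)
  d <- as.matrix(dist(xy, method = "manhattan"))
  A <- (abs(d - 1) < 1e-9) * 1
  if (any(rowSums(A) == 0)) stop("isolated unit: not a connected lattice")
  spatial_weights(A, ids = coords$unit_id, standardization = standardization,
                  kind = "binary_contiguity")
}
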