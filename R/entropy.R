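# Entropy weight method, composite resource index, and CHRDI.

#' Min-max standardization with orientation
#'
#' Positive indicators map to `(x - min)/(max - min)`, negative indicators
#' to `(max - x)/(max - min)`, so larger standardized values always mean a
#' better endowment.
#'
#' @param x numeric vector (one indicator across units), length >= 2.
#' @param orientation `"positive"` or `"negative"`.
#' @return vector in \[0, 1\] attaining both endpoints.
#' @export
minmax_standardize <- function(x, orientation = c("positive", "negative")) {
  orientation <- match.arg(orientation)
  if (length(x) < 2) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("non-finite values")
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate column: all values equal (max == min)")
  if (orientation == "positive") (x - rng[1]) / (rng[2] - rng[1])
  else (rng[2] - x) / (rng[2] - rng[1])
}

#' Entropy weights for a standardized indicator matrix
#'
#' Computes, per indicator j over m units: shares
#' `P_ij = X_ij / sum_i X_ij`, Shannon entropy
#' `e_j = -(1/ln m) * sum_i P_ij ln P_ij` (with `0 ln 0 := 0`), difference
#' coefficient `g_j = 1 - e_j`, and weights `W_j = g_j / sum_j g_j`.
#' Indicators whose shares are spread unevenly across units (low entropy)
#' carry more information and receive larger weights.
#'
#' @param X units x indicators matrix of standardized values in \[0, 1\].
#' @param zero_shift optional small constant added to every entry before
#'   computing shares (some applied work shifts zeros by e.g. 1e-4 instead
#'   of relying on the 0 ln 0 limit); default 0 uses the limit convention.
#' @return list of class `entropy_weights`: `weights`, `entropy`,
#'   `diff_coef` (named by indicator).
#' @export
entropy_weights <- function(X, zero_shift = 0) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2) stop("need at least 2 units")
  if (any(!is.finite(X)) || any(X < 0)) stop("X must be nonnegative finite")
  if (zero_shift > 0) X <- X + zero_shift
  cs <- colSums(X)
  if (any(cs == 0))
    stop("all-zero indicator column(s): ",
         paste(colnames(X)[cs == 0], collapse = ", "))
  P <- sweep(X, 2, cs, "/")
  plogp <- P * log(P)
  plogp[P == 0] <- 0                       # 0 * log(0) := 0
  e <- -colSums(plogp) / log(m)
  g <- 1 - e
  if (all(g <= .Machine$double.eps * 10))
    stop("all indicators maximally even (g_j = 0 for all j); ",
         "entropy weights undefined, supply manual weights instead")
  w <- g / sum(g)
  nm <- colnames(X)
  structure(list(weights = setNames(w, nm), entropy = setNames(e, nm),
                 diff_coef = setNames(g, nm)),
            class = "entropy_weights")
}

#' Weighted composite resource index
#'
#' `u_i = sum_j W_j X_ij` on standardized values, so `u` lies in \[0, 1\].
#'
#' @param X units x indicators standardized matrix.
#' @param weights an `entropy_weights` object or a named/plain numeric
#'   vector summing to 1.
#' @return numeric vector `u`, named by unit.
#' @export
composite_index <- function(X, weights) {
  X <- as.matrix(X)
  w <- if (inherits(weights, "entropy_weights")) weights$weights else weights
  if (!is.null(names(w)) && !is.null(colnames(X))) {
    if (!setequal(names(w), colnames(X)))
      stop("indicator sets of X and weights differ")
    w <- w[colnames(X)]
  } else if (length(w) != ncol(X)) {
    stop("weight length does not match indicator count")
  }
  drop(X %*% w)
}

#' Comprehensive health resource density index
#'
#' Geometric mean of resources per thousand population and resources per
#' square kilometre:
#' `CHRDI = sqrt((u / pop) * (u / area)) = u / sqrt(pop * area)`.
#' Degree-1 homogeneous in `u`.
#'
#' @param u composite resource index (>= 0).
#' @param population_thousands resident population in thousands (> 0).
#' @param area_km2 land area in square kilometres (> 0).
#' @return nonnegative numeric vector.
#' @export
chrdi <- function(u, population_thousands, area_km2) {
  if (any(u < 0)) stop("u must be nonnegative")
  if (any(population_thousands <= 0)) stop("population must be positive")
  if (any(area_km2 <= 0)) stop("area must be positive")
  u / sqrt(population_thousands * area_km2)
}

#' Entropy-weighted composite index and CHRDI for a whole panel
#'
#' Runs standardization, entropy weighting, the composite index and CHRDI
#' per year (default) or on the pooled panel. Population and area are taken
#' from the panel's `population` (thousands) and `area` (km2) indicators
#' and must be constant checks are left to the caller.
#'
#' @param panel an `indicator_panel`.
#' @param indicators resource indicator names to weight.
#' @param population,area indicator names holding population (thousands)
#'   and area (km2).
#' @param mode `"per_year"` (standardize and weight within each year) or
#'   `"pooled"` (one standardization/weighting over all unit-years).
#' @param zero_shift passed to [entropy_weights()].
#' @return data.frame (unit_id, year, u, chrdi) with a `weights` attribute
#'   holding a (year, indicator, entropy, diff_coef, weight) table.
#' @export
chrdi_series <- function(panel, indicators, population = "population",
                         area = "area", mode = c("per_year", "pooled"),
                         zero_shift = 0) {
  mode <- match.arg(mode)
  ori <- attr(panel, "orientation")[indicators]
  ori[is.na(ori)] <- "positive"
  years <- sort(unique(panel$year))
  std_year <- function(yr) {
    X <- panel_matrix(panel, indicators, yr)
    for (j in seq_along(indicators))
      X[, j] <- minmax_standardize(X[, j], ori[j])
    X
  }
  if (mode == "pooled") {
    Xs <- do.call(rbind, lapply(years, function(yr)
      panel_matrix(panel, indicators, yr)))
    for (j in seq_along(indicators))
      Xs[, j] <- minmax_standardize(Xs[, j], ori[j])
    ew <- entropy_weights(Xs, zero_shift = zero_shift)
    u_all <- composite_index(Xs, ew)
    wtab <- data.frame(year = NA_integer_, indicator = indicators,
                       entropy = unname(ew$entropy),
                       diff_coef = unname(ew$diff_coef),
                       weight = unname(ew$weights))
    res <- do.call(rbind, lapply(seq_along(years), function(k) {
      units <- sort(unique(panel$unit_id))
      idx <- (k - 1) * length(units) + seq_along(units)
      data.frame(unit_id = units, year = years[k], u = unname(u_all[idx]))
    }))
  } else {
    pieces <- lapply(years, function(yr) {
      Xs <- std_year(yr)
      ew <- entropy_weights(Xs, zero_shift = zero_shift)
      u <- composite_index(Xs, ew)
      list(res = data.frame(unit_id = rownames(Xs), year = yr,
                            u = unname(u)),
           w = data.frame(year = yr, indicator = indicators,
                          entropy = unname(ew$entropy),
                          diff_coef = unname(ew$diff_coef),
                          weight = unname(ew$weights)))
    })
    res <- do.call(rbind, lapply(pieces, `[[`, "res"))
    wtab <- do.call(rbind, lapply(pieces, `[[`, "w"))
  }
  pop <- panel[panel$indicator == population, c("unit_id", "year", "value")]
  ar <- panel[panel$indicator == area, c("unit_id", "year", "value")]
  if (!nrow(pop) || !nrow(ar))
    stop("panel lacks '", population, "' or '", area, "' indicator")
  key <- function(d) paste(d$unit_id, d$year)
  res$chrdi <- chrdi(res$u,
                     pop$value[match(key(res), key(pop))],
                     ar$value[match(key(res), key(ar))])
  rownames(res) <- NULL
  attr(res, "weights") <- wtab
  res
}
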