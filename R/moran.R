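# Global/local Moran's I, inference, cluster labels, quadrant classification.

as_weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$matrix else as.matrix(W)
}

#' Global Moran's I
#'
#' `I = [sum_ij w_ij (x_i - xbar)(x_j - xbar)] /
#'      [(1/N) sum_i (x_i - xbar)^2 * sum_ij w_ij]`.
#' The formula normalizes by the total weight, so it is valid for both raw
#' and row-standardized weights. Under the no-autocorrelation null,
#' `E(I) = -1/(N - 1)`.
#'
#' @param x numeric vector (one value per unit, in `W` id order).
#' @param W a `spatial_weights` object or plain matrix.
#' @return list with `I`, `expected`, `n`, `S0` (total weight).
#' @export
global_moran <- function(x, W) {
  Wm <- as_weights_matrix(W)
  n <- length(x)
  if (n < 3) stop("need at least 3 units")
  if (nrow(Wm) != n) stop("length of x must match weight matrix dimension")
  if (var(x) == 0) stop("x is constant: Moran's I undefined (zero variance)")
  s0 <- sum(Wm)
  if (s0 == 0) stop("all-zero weight matrix")
  z <- x - mean(x)
  I <- (n / s0) * drop(z %*% Wm %*% z) / sum(z^2)
  list(I = I, expected = -1 / (n - 1), n = n, S0 = s0)
}

moran_closed_form_sd <- function(x, Wm, method) {
  n <- length(x)
  s0 <- sum(Wm)
  s1 <- 0.5 * sum((Wm + t(Wm))^2)
  s2 <- sum((rowSums(Wm) + colSums(Wm))^2)
  ei <- -1 / (n - 1)
  if (method == "normality") {
    v <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - ei^2
  } else {                                 # randomization (kurtosis-adjusted)
    z <- x - mean(x)
    b2 <- n * sum(z^4) / sum(z^2)^2
    v <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
            b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
  }
  sqrt(v)
}

#' Moran's I test of spatial autocorrelation
#'
#' Closed-form variance under the normality or randomization assumption, or
#' an empirical permutation null from random relabelings of `x`. The default
#' alternative is positive autocorrelation (one-sided, greater).
#'
#' @param x,W as in [global_moran()].
#' @param method `"randomization"` (kurtosis-adjusted variance, default),
#'   `"normality"`, or `"permutation"`.
#' @param nsim permutations for `method = "permutation"` (>= 99).
#' @param seed optional seed for the permutation null.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return list of class `moran_test`: `I`, `expected`, `sd`, `z`, `p`,
#'   `method`, `n`, `nsim`.
#' @export
moran_test <- function(x, W, method = c("randomization", "normality",
                                        "permutation"),
                       nsim = 999, seed = NULL,
                       alternative = c("greater", "less", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  Wm <- as_weights_matrix(W)
  gm <- global_moran(x, Wm)
  if (method == "permutation") {
    if (nsim < 99) stop("need at least 99 permutations")
    if (!is.null(seed)) set.seed(seed)
    sims <- vapply(seq_len(nsim),
                   function(i) global_moran(sample(x), Wm)$I, numeric(1))
    sdI <- sd(sims)
    zstat <- (gm$I - mean(sims)) / sdI
    p <- switch(alternative,
                greater = (sum(sims >= gm$I) + 1) / (nsim + 1),
                less = (sum(sims <= gm$I) + 1) / (nsim + 1),
                two.sided = (sum(abs(sims - mean(sims)) >=
                                   abs(gm$I - mean(sims))) + 1) / (nsim + 1))
  } else {
    sdI <- moran_closed_form_sd(x, Wm, method)
    zstat <- (gm$I - gm$expected) / sdI
    p <- switch(alternative,
                greater = pnorm(zstat, lower.tail = FALSE),
                less = pnorm(zstat),
                two.sided = 2 * pnorm(abs(zstat), lower.tail = FALSE))
  }
  structure(list(I = gm$I, expected = gm$expected, sd = sdI, z = zstat,
                 p = p, method = method, n = gm$n,
                 nsim = if (method == "permutation") nsim else NA_integer_),
            class = "moran_test")
}

#' Local Moran's I with cluster labels
#'
#' `I_i = N (x_i - xbar) sum_j w_ij (x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Cluster labels follow the sign pattern of the own deviation and the
#' spatial lag of deviations: (+,+) HH, (+,-) HL, (-,-) LL, (-,+) LH; units
#' whose conditional-permutation p value is >= `alpha` are labelled NS.
#' The local statistics sum to `I_global * sum_ij w_ij` (identity of the two
#' formulas).
#'
#' @param x,W as in [global_moran()].
#' @param alpha significance filter for cluster labelling.
#' @param nsim conditional permutations per unit.
#' @param seed optional seed.
#' @param alternative p-value sidedness for each unit; default two-sided.
#' @return data.frame (unit, Ii, p, cluster) with attribute `alpha`.
#' @export
local_moran <- function(x, W, alpha = 0.05, nsim = 999, seed = NULL,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  Wm <- as_weights_matrix(W)
  n <- length(x)
  if (n < 3) stop("need at least 3 units")
  if (var(x) == 0) stop("x is constant: local Moran's I undefined")
  if (!is.null(seed)) set.seed(seed)
  z <- x - mean(x)
  m2 <- sum(z^2)
  lag <- drop(Wm %*% z)
  Ii <- n * z * lag / m2
  # conditional permutation: hold z_i fixed, permute the remaining values
  p <- numeric(n)
  for (i in seq_len(n)) {
    wi <- Wm[i, -i]
    zi <- z[-i]
    sims <- vapply(seq_len(nsim), function(b)
      n * z[i] * sum(wi * sample(zi)) / m2, numeric(1))
    p[i] <- switch(alternative,
                   greater = (sum(sims >= Ii[i]) + 1) / (nsim + 1),
                   less = (sum(sims <= Ii[i]) + 1) / (nsim + 1),
                   two.sided = {
                     ctr <- sims - mean(sims)
                     (sum(abs(ctr) >= abs(Ii[i] - mean(sims))) + 1) /
                       (nsim + 1)
                   })
  }
  cluster <- ifelse(z > 0 & lag > 0, "HH",
                    ifelse(z > 0 & lag <= 0, "HL",
                           ifelse(z <= 0 & lag <= 0, "LL", "LH")))
  cluster[p >= alpha] <- "NS"
  ids <- if (inherits(W, "spatial_weights")) W$ids else
    (names(x) %||% as.character(seq_len(n)))
  out <- data.frame(unit = ids, Ii = Ii, p = p,
                    cluster = factor(cluster,
                                     levels = c("HH", "HL", "LL", "LH",
                                                "NS")),
                    row.names = NULL)
  attr(out, "alpha") <- alpha
  out
}

#' Allocation-efficiency quadrant classification
#'
#' Crosses a resource-allocation axis (CHRDI) with an efficiency axis, both
#' centred at their cross-unit means: quadrant I = high allocation & high
#' efficiency, II = low/high, III = low/low, IV = high/low. Values exactly
#' at the mean count as "low".
#'
#' @param chrdi,efficiency named numeric vectors over the same unit set.
#' @return factor (levels I, II, III, IV) named by unit.
#' @export
quadrant_classify <- function(chrdi, efficiency) {
  if (length(chrdi) < 2) stop("need at least 2 units")
  if (is.null(names(chrdi)) || is.null(names(efficiency))) {
    if (length(chrdi) != length(efficiency))
      stop("unit sets differ between chrdi and efficiency")
  } else {
    if (!setequal(names(chrdi), names(efficiency)))
      stop("unit sets differ between chrdi and efficiency")
    efficiency <- efficiency[names(chrdi)]
  }
  hi_c <- chrdi > mean(chrdi)
  hi_e <- efficiency > mean(efficiency)
  q <- ifelse(hi_c & hi_e, "I",
              ifelse(!hi_c & hi_e, "II",
                     ifelse(!hi_c & !hi_e, "III", "IV")))
  setNames(factor(q, levels = c("I", "II", "III", "IV")),
           names(chrdi) %||% NULL)
}
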