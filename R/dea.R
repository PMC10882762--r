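# Input-oriented DEA and Simar-Wilson smoothed-bootstrap bias correction.

#' Construct a DEA instance
#'
#' @param inputs n x p matrix of strictly positive inputs.
#' @param outputs n x q matrix of nonnegative outputs, each DMU having at
#'   least one positive output.
#' @param labels optional DMU labels (default rownames or 1..n).
#' @return list of class `dea_instance` with `inputs`, `outputs`, `labels`.
#' @export
dea_instance <- function(inputs, outputs, labels = NULL) {
  inputs <- as.matrix(inputs)
  outputs <- as.matrix(outputs)
  if (nrow(inputs) != nrow(outputs))
    stop("inputs and outputs must have the same number of DMUs")
  if (any(!is.finite(inputs)) || any(!is.finite(outputs)))
    stop("non-finite entries in DEA data")
  if (any(inputs <= 0)) stop("all inputs must be strictly positive")
  if (any(outputs < 0)) stop("outputs must be nonnegative")
  if (any(rowSums(outputs > 0) == 0))
    stop("every DMU needs at least one positive output")
  if (is.null(labels))
    labels <- rownames(inputs) %||% as.character(seq_len(nrow(inputs)))
  structure(list(inputs = unname(inputs), outputs = unname(outputs),
                 labels = as.character(labels)),
            class = "dea_instance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Input-oriented DEA technical efficiency
#'
#' Solves, for each DMU i, the envelopment program
#' min theta s.t. theta*x_i - X'lambda >= 0, Y'lambda >= y_i, lambda >= 0
#' (VRS adds sum(lambda) = 1). A score of 1 means the DMU lies on the
#' empirical best-practice frontier.
#'
#' @param instance a `dea_instance`.
#' @param rts returns to scale: `"vrs"` (variable) or `"crs"` (constant).
#' @param eval_instance optional second `dea_instance` whose DMUs are scored
#'   against `instance`'s frontier (used by the bootstrap); defaults to
#'   `instance` itself.
#' @return numeric vector of efficiencies in (0, 1\] (values may exceed 1
#'   when scoring external DMUs above the reference frontier), named by DMU.
#' @export
dea_te <- function(instance, rts = c("vrs", "crs"), eval_instance = instance) {
  rts <- match.arg(rts)
  stopifnot(inherits(instance, "dea_instance"),
            inherits(eval_instance, "dea_instance"))
  th <- .dea_scores_cpp(instance$inputs, instance$outputs,
                        eval_instance$inputs, eval_instance$outputs,
                        rts == "vrs")
  th <- as.numeric(th)
  if (any(is.nan(th)))
    stop("infeasible envelopment LP for DMU ",
         eval_instance$labels[which(is.nan(th))[1]])
  # clip solver noise: self-evaluation is radial, theta in (0, 1]
  if (identical(instance, eval_instance)) th <- pmin(pmax(th, 1e-9), 1)
  setNames(th, eval_instance$labels)
}

# Silverman rule-of-thumb bandwidth on the reflected efficiency sample
silverman_bw <- function(x) {
  n <- length(x)
  s <- min(sd(x), IQR(x) / 1.349)
  if (s == 0) s <- sd(x)
  0.9 * s * n^(-1 / 5)
}

#' Simar-Wilson homogeneous smoothed bootstrap for DEA
#'
#' Estimates and removes the upward bias of DEA efficiency scores. The DEA
#' frontier is estimated from the data, so scores are biased towards 1; the
#' smoothed bootstrap resamples efficiencies from a kernel density estimate
#' of the scores reflected about 1 (to respect the boundary), rescales the
#' inputs into pseudo-data, re-solves the DEA against each pseudo-reference
#' set, and subtracts the resulting bias estimate.
#'
#' Per replicate: draw from the reflected sample with replacement, add
#' Gaussian kernel noise with Silverman bandwidth `h`, shrink by the
#' variance-correction factor `1/sqrt(1 + h^2/var)`, fold back into (0, 1],
#' form pseudo-inputs `x*_j = (theta_j/theta*_j) x_j`, and score each
#' original DMU against the pseudo-frontier.
#'
#' @param instance a `dea_instance`.
#' @param rts `"vrs"` or `"crs"`.
#' @param B number of bootstrap replicates (>= 100).
#' @param level two-sided confidence level for the percentile interval.
#' @param seed optional integer seed.
#' @return data.frame of class `efficiency_result` with columns `dmu`,
#'   `theta`, `theta_bc` (bias-corrected), `bias`, `ci_low`, `ci_high`;
#'   attributes `rts`, `B`, `bandwidth`, `level`, `seed`.
#' @export
simar_wilson <- function(instance, rts = c("vrs", "crs"), B = 2000,
                         level = 0.95, seed = NULL) {
  rts <- match.arg(rts)
  if (B < 100) stop("B must be at least 100")
  if (B * (1 - level) / 2 < 1)
    stop("B too small for a ", level, " percentile interval")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(instance$inputs)
  theta <- dea_te(instance, rts)
  if (all(theta >= 1 - 1e-12))
    stop("all DMUs on the frontier (theta = 1): no variation to smooth")
  refl <- c(theta, 2 - theta)              # reflect about the boundary at 1
  h <- silverman_bw(refl)
  s2 <- var(refl)
  boot <- matrix(NA_real_, n, B)
  for (b in seq_len(B)) {
    beta <- sample(refl, n, replace = TRUE)
    draw <- mean(beta) +
      (beta + h * rnorm(n) - mean(beta)) / sqrt(1 + h^2 / s2)
    draw <- ifelse(draw > 1, 2 - draw, draw)           # fold into (0, 1]
    draw <- pmin(pmax(draw, 1e-6), 1)
    pseudo <- dea_instance(instance$inputs * (theta / draw),
                           instance$outputs, instance$labels)
    boot[, b] <- .dea_scores_cpp(pseudo$inputs, pseudo$outputs,
                                 instance$inputs, instance$outputs,
                                 rts == "vrs")
  }
  if (any(is.nan(boot)))
    boot[is.nan(boot)] <- NA_real_
  bias <- rowMeans(boot, na.rm = TRUE) - theta
  theta_bc <- theta - bias
  alpha <- (1 - level) / 2
  ci <- t(apply(2 * theta - boot, 1, quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE))
  out <- data.frame(dmu = instance$labels, theta = unname(theta),
                    theta_bc = unname(theta_bc), bias = unname(bias),
                    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                    row.names = NULL)
  structure(out, rts = rts, B = B, bandwidth = h, level = level,
            seed = seed, class = c("efficiency_result", "data.frame"))
}

#' Year-by-year DEA with bootstrap correction on an indicator panel
#'
#' Builds one DEA cross-section per year from named input and output
#' indicators and runs [dea_te()] plus [simar_wilson()] within each year.
#'
#' @param panel an `indicator_panel` containing all named indicators.
#' @param inputs,outputs character vectors of indicator names.
#' @param rts,B,level,seed passed to [simar_wilson()]; each year uses an
#'   independent seed derived from `seed` so years are reproducible in
#'   isolation.
#' @return data.frame (unit_id, year, traditional, corrected, bias, ci_low,
#'   ci_high).
#' @export
efficiency_panel <- function(panel, inputs, outputs, rts = c("vrs", "crs"),
                             B = 2000, level = 0.95, seed = NULL) {
  rts <- match.arg(rts)
  years <- sort(unique(panel$year))
  out <- lapply(seq_along(years), function(k) {
    yr <- years[k]
    X <- panel_matrix(panel, inputs, yr)
    Y <- panel_matrix(panel, outputs, yr)
    inst <- dea_instance(X, Y, labels = rownames(X))
    sw <- simar_wilson(inst, rts = rts, B = B, level = level,
                       seed = if (is.null(seed)) NULL else seed + k - 1L)
    data.frame(unit_id = sw$dmu, year = yr, traditional = sw$theta,
               corrected = sw$theta_bc, bias = sw$bias,
               ci_low = sw$ci_low, ci_high = sw$ci_high)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
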