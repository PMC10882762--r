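# Fixed-effects spatial Durbin / lag / error panel models by maximum
# likelihood, impact decomposition, LR nesting tests, Hausman screen, VIF.

# within-transformation (demeaning) operators for a balanced N x T panel,
# observations stacked year-major (all units for year 1, then year 2, ...)
demean_panel <- function(M, n, t, effects) {
  M <- as.matrix(M)
  if (effects %in% c("unit", "twoway")) {
    for (i in seq_len(n)) {
      idx <- i + n * (seq_len(t) - 1)
      M[idx, ] <- sweep(M[idx, , drop = FALSE], 2,
                        colMeans(M[idx, , drop = FALSE]))
    }
  }
  if (effects %in% c("time", "twoway")) {
    for (s in seq_len(t)) {
      idx <- (s - 1) * n + seq_len(n)
      M[idx, ] <- sweep(M[idx, , drop = FALSE], 2,
                        colMeans(M[idx, , drop = FALSE]))
    }
  }
  M
}

# log|I - rho*W| from the (possibly complex) eigenvalues of W
logdet_factory <- function(Wm) {
  ev <- eigen(Wm, only.values = TRUE)$values
  function(rho) sum(log(abs(1 - rho * ev)))
}

rho_interval <- function(Wm) {
  ev <- eigen(Wm, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < 1e-8])
  lo <- if (any(re < 0)) 1 / min(re) else -1
  hi <- if (any(re > 0)) 1 / max(re) else 1
  c(lo + 1e-6, hi - 1e-6)
}

panel_arrays <- function(data, response, regressors, W, unit, time) {
  Wm <- as_weights_matrix(W)
  ids <- if (inherits(W, "spatial_weights")) W$ids else rownames(Wm)
  if (is.null(ids)) ids <- sort(unique(as.character(data[[unit]])))
  n <- length(ids)
  yrs <- sort(unique(data[[time]]))
  t <- length(yrs)
  if (nrow(data) != n * t)
    stop("unbalanced panel: expected ", n * t, " rows, got ", nrow(data))
  ord <- order(match(data[[time]], yrs), match(data[[unit]], ids))
  data <- data[ord, , drop = FALSE]
  if (any(is.na(match(data[[unit]], ids))))
    stop("units in data not present in W")
  y <- as.numeric(data[[response]])
  X <- as.matrix(data[regressors])
  if (any(!is.finite(y)) || any(!is.finite(X))) stop("non-finite model data")
  list(y = y, X = X, Wm = Wm, n = n, t = t, ids = ids, yrs = yrs)
}

apply_W <- function(Wm, M, n, t) {
  M <- as.matrix(M)
  out <- M
  for (s in seq_len(t)) {
    idx <- (s - 1) * n + seq_len(n)
    out[idx, ] <- Wm %*% M[idx, , drop = FALSE]
  }
  out
}

#' Fit a fixed-effects spatial panel model by maximum likelihood
#'
#' Estimates the spatial Durbin model `Y = rho*W*Y + X*beta + W*X*theta +
#' mu + eps` (or its spatial-lag restriction `theta = 0`, or the spatial
#' error model `Y = X*beta + u, u = rho*W*u + eps`) on a balanced panel,
#' after within-transforming out the chosen fixed effects. The likelihood
#' follows the orthonormal-transformation convention for short fixed-effects
#' panels: the effective sample size is `N(T-1)` under unit effects (and
#' analogously for time/two-way), which keeps `sigma2` and likelihood-ratio
#' statistics calibrated when `T` is small. The likelihood is
#' concentrated: for each candidate `rho` the slope coefficients come from
#' least squares and `log|I - rho*W|` is evaluated from the eigenvalues of
#' `W` (computed once), then `rho` is found by one-dimensional optimization
#' over its stationarity interval.
#'
#' @param data data.frame in long format with unit, time, response and
#'   regressor columns; must form a balanced panel over `W`'s units.
#' @param response,regressors column names.
#' @param W `spatial_weights` (row-standardized recommended) or matrix whose
#'   row order defines the unit order.
#' @param effects fixed-effects mode: `"unit"` (default), `"time"`,
#'   `"twoway"`, `"none"`.
#' @param model `"sdm"`, `"slm"` or `"sem"`.
#' @param unit,time column names of the unit and time identifiers.
#' @return object of class `sdm_fit`: `rho`, `coefficients` (beta and, for
#'   SDM, the `W.`-prefixed theta), `sigma2`, `loglik`, `vcov` (slopes +
#'   rho), `fitted`, `residuals`, `R2_within`, `R2_corr`, `fe` (recovered
#'   unit effects when applicable), dims `N`, `T`, plus call metadata.
#' @export
fit_sdm <- function(data, response, regressors, W,
                    effects = c("unit", "time", "twoway", "none"),
                    model = c("sdm", "slm", "sem"),
                    unit = "unit_id", time = "year") {
  effects <- match.arg(effects)
  model <- match.arg(model)
  pa <- panel_arrays(data, response, regressors, W, unit, time)
  n <- pa$n; t <- pa$t; k <- ncol(pa$X)
  nt <- n * t
  if (nt < 2 * k + 12)
    stop("panel too small for ", k, " regressors")
  WX <- apply_W(pa$Wm, pa$X, n, t)
  colnames(WX) <- paste0("W.", regressors)
  Z <- switch(model, sdm = cbind(pa$X, WX), cbind(pa$X))
  colnames(Z)[seq_len(k)] <- regressors
  if (effects == "none") Z <- cbind(`(Intercept)` = 1, Z)
  Wy <- apply_W(pa$Wm, pa$y, n, t)
  ys <- demean_panel(pa$y, n, t, effects)
  Zs <- demean_panel(Z, n, t, effects)
  Wys <- demean_panel(Wy, n, t, effects)
  qrZ <- qr(Zs)
  if (qrZ$rank < ncol(Zs)) {
    bad <- colnames(Zs)[qrZ$pivot[(qrZ$rank + 1):ncol(Zs)]]
    stop("collinear regressor column(s): ", paste(bad, collapse = ", "))
  }
  ld <- logdet_factory(pa$Wm)
  iv <- rho_interval(pa$Wm)
  # Lee-Yu transformation likelihood: the within transformation projects
  # onto an orthonormal subspace, so the effective sample is smaller than
  # NT and the Jacobian term enters once per transformed cross-section.
  # Using the effective counts keeps sigma2 (and LR statistics between
  # nested spatial fits) calibrated in short panels.
  t_ld <- if (effects %in% c("unit", "twoway")) t - 1L else t
  n_eff <- switch(effects,
                  unit = n * (t - 1L),
                  time = (n - 1L) * t,
                  twoway = (n - 1L) * (t - 1L),
                  none = nt)
  const <- -(n_eff / 2) * (log(2 * pi) + 1)
  if (model %in% c("sdm", "slm")) {
    e0 <- ys - Zs %*% qr.coef(qrZ, ys)
    e1 <- Wys - Zs %*% qr.coef(qrZ, Wys)
    cll <- function(rho) {
      ee <- e0 - rho * e1
      const + t_ld * ld(rho) - (n_eff / 2) * log(sum(ee^2) / n_eff)
    }
    opt <- optimize(cll, interval = iv, maximum = TRUE, tol = 1e-10)
    rho <- opt$maximum
    delta <- drop(qr.coef(qrZ, ys - rho * Wys))
    resid <- drop(ys - rho * Wys - Zs %*% delta)
    loglik <- opt$objective
  } else {                                 # SEM via spatially filtered GLS
    cll <- function(rho) {
      yt <- ys - rho * apply_W(pa$Wm, ys, n, t)
      Zt <- Zs - rho * apply_W(pa$Wm, Zs, n, t)
      ee <- yt - Zt %*% qr.coef(qr(Zt), yt)
      const + t_ld * ld(rho) - (n_eff / 2) * log(sum(ee^2) / n_eff)
    }
    opt <- optimize(cll, interval = iv, maximum = TRUE, tol = 1e-10)
    rho <- opt$maximum
    yt <- ys - rho * apply_W(pa$Wm, ys, n, t)
    Zt <- Zs - rho * apply_W(pa$Wm, Zs, n, t)
    delta <- drop(qr.coef(qr(Zt), yt))
    resid <- drop(yt - Zt %*% delta)
    loglik <- opt$objective
  }
  names(delta) <- colnames(Zs)
  if (abs(rho - iv[1]) < 1e-4 || abs(rho - iv[2]) < 1e-4)
    warning("rho estimate at the boundary of its stationarity interval")
  sigma2 <- sum(resid^2) / n_eff
  # vcov from the numerical Hessian of the full within log-likelihood
  nll <- if (model %in% c("sdm", "slm")) {
    function(par) {
      d <- par[seq_along(delta)]; r <- par[length(delta) + 1]
      s2 <- exp(par[length(delta) + 2])
      ee <- ys - r * Wys - Zs %*% d
      -(-(n_eff / 2) * log(2 * pi * s2) + t_ld * ld(r) -
          sum(ee^2) / (2 * s2))
    }
  } else {
    function(par) {
      d <- par[seq_along(delta)]; r <- par[length(delta) + 1]
      s2 <- exp(par[length(delta) + 2])
      yt2 <- ys - r * apply_W(pa$Wm, ys, n, t)
      Zt2 <- Zs - r * apply_W(pa$Wm, Zs, n, t)
      ee <- yt2 - Zt2 %*% d
      -(-(n_eff / 2) * log(2 * pi * s2) + t_ld * ld(r) -
          sum(ee^2) / (2 * s2))
    }
  }
  H <- numDeriv::hessian(nll, c(delta, rho, log(sigma2)))
  vc <- tryCatch(solve(H), error = function(e) MASS_ginv(H))
  # delta-method back from log(sigma2); keep (slopes, rho) block
  pn <- c(names(delta), "rho")
  vcov <- vc[seq_along(pn), seq_along(pn), drop = FALSE]
  dimnames(vcov) <- list(pn, pn)
  fitted_within <- drop(ys - resid)
  r2w <- 1 - sum(resid^2) / sum((ys - mean(ys))^2)
  r2c <- suppressWarnings(cor(fitted_within, ys)^2)
  fe <- NULL
  if (effects %in% c("unit", "twoway")) {
    raw <- pa$y - rho * Wy - Z %*% delta
    fe <- tapply(raw, rep(pa$ids, t), mean)
  }
  structure(list(rho = rho, coefficients = delta, sigma2 = sigma2,
                 loglik = loglik, vcov = vcov, model = model,
                 effects = effects, response = response,
                 regressors = regressors, N = n, T = t,
                 residuals = resid, fitted = fitted_within,
                 R2_within = r2w, R2_corr = r2c, fe = fe,
                 rho_interval = iv, W = pa$Wm),
            class = "sdm_fit")
}

# Moore-Penrose pseudo-inverse via SVD (fallback for near-singular Hessians)
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(toupper(x$model), "fit (", x$effects, "effects ): N =", x$N,
      "T =", x$T, "\n")
  cat("rho =", format(x$rho, digits = 4),
      " sigma2 =", format(x$sigma2, digits = 4),
      " loglik =", format(x$loglik, digits = 6), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Direct, indirect and total impacts of an SDM/SLM fit
#'
#' For regressor k the matrix of partial effects is
#' `S_k(W) = (I - rho*W)^{-1} (I*beta_k + W*theta_k)`; the direct effect is
#' the average diagonal element, the total effect the average row sum, and
#' the indirect (spillover) effect their difference. Inference simulates
#' `(coefficients, rho)` from the estimated sampling distribution and
#' recomputes the three summaries per draw.
#'
#' @param fit an `sdm_fit` (model `"sdm"` or `"slm"`).
#' @param nsim simulation draws for standard errors (0 = point estimates
#'   only).
#' @param seed optional seed.
#' @return data.frame of class `sdm_impacts` with one row per regressor and
#'   columns `direct`, `indirect`, `total` plus `*_se`, `*_z`, `*_p` when
#'   `nsim > 0`.
#' @export
sdm_impacts <- function(fit, nsim = 1000, seed = NULL) {
  if (!inherits(fit, "sdm_fit")) stop("fit must be an sdm_fit")
  if (fit$model == "sem") stop("impacts are defined for sdm/slm fits")
  Wm <- fit$W
  n <- nrow(Wm)
  iv <- fit$rho_interval
  point <- impact_summaries(fit$rho, fit$coefficients, fit$regressors, Wm)
  out <- as.data.frame(point)
  if (nsim > 0) {
    if (!is.null(seed)) set.seed(seed)
    pn <- c(names(fit$coefficients), "rho")
    V <- fit$vcov[pn, pn]
    L <- tryCatch(chol(V), error = function(e)
      chol(V + diag(1e-10, nrow(V))))
    mu <- c(fit$coefficients, fit$rho)
    sims <- array(NA_real_, c(length(fit$regressors), 3, nsim))
    for (s in seq_len(nsim)) {
      par <- drop(mu + t(L) %*% rnorm(length(mu)))
      r <- min(max(par[length(par)], iv[1]), iv[2])
      co <- setNames(par[-length(par)], names(fit$coefficients))
      sims[, , s] <- impact_summaries(r, co, fit$regressors, Wm)
    }
    for (j in 1:3) {
      nm <- colnames(point)[j]
      se <- apply(sims[, j, , drop = FALSE], 1, sd)
      out[[paste0(nm, "_se")]] <- se
      out[[paste0(nm, "_z")]] <- point[, j] / se
      out[[paste0(nm, "_p")]] <- 2 * pnorm(-abs(point[, j] / se))
    }
  }
  rownames(out) <- fit$regressors
  class(out) <- c("sdm_impacts", "data.frame")
  out
}

impact_summaries <- function(rho, coefs, regressors, Wm) {
  n <- nrow(Wm)
  A <- solve(diag(n) - rho * Wm)
  k <- length(regressors)
  res <- matrix(NA_real_, k, 3,
                dimnames = list(regressors, c("direct", "indirect", "total")))
  for (j in seq_len(k)) {
    bk <- coefs[[regressors[j]]]
    tk <- coefs[[paste0("W.", regressors[j])]]
    S <- if (is.null(tk) || is.na(tk)) A * bk else A %*% (diag(bk, n) + Wm * tk)
    direct <- mean(diag(S))
    total <- mean(rowSums(S))
    res[j, ] <- c(direct, total - direct, total)
  }
  res
}

#' Likelihood-ratio test between nested spatial fits
#'
#' `LR = 2 (loglik_full - loglik_restricted)`, chi-square with df equal to
#' the difference in parameter counts. The SDM nests the SLM (`theta = 0`)
#' and, via the common-factor restriction `theta = -rho*beta`, the SEM.
#'
#' @param full,restricted `sdm_fit` objects on identical data.
#' @return list with `statistic`, `df`, `p`.
#' @export
lr_test <- function(full, restricted) {
  if (!inherits(full, "sdm_fit") || !inherits(restricted, "sdm_fit"))
    stop("both arguments must be sdm_fit objects")
  if (full$N != restricted$N || full$T != restricted$T ||
      full$response != restricted$response)
    stop("fits are not on identical data: cannot compare")
  df <- length(full$coefficients) - length(restricted$coefficients)
  if (df <= 0) stop("'full' does not nest 'restricted'")
  stat <- 2 * (full$loglik - restricted$loglik)
  list(statistic = stat, df = df, p = pchisq(max(stat, 0), df,
                                             lower.tail = FALSE))
}

#' SDM-vs-SLM and SDM-vs-SEM likelihood-ratio tests
#'
#' @param data,response,regressors,W,effects,unit,time as in [fit_sdm()].
#' @return list with the three fits and the two LR results.
#' @export
lr_tests <- function(data, response, regressors, W, effects = "unit",
                     unit = "unit_id", time = "year") {
  f_sdm <- fit_sdm(data, response, regressors, W, effects, "sdm", unit, time)
  f_slm <- fit_sdm(data, response, regressors, W, effects, "slm", unit, time)
  f_sem <- fit_sdm(data, response, regressors, W, effects, "sem", unit, time)
  list(sdm = f_sdm, slm = f_slm, sem = f_sem,
       lr_slm = lr_test(f_sdm, f_slm), lr_sem = lr_test(f_sdm, f_sem))
}

#' Hausman screen: fixed vs random effects (non-spatial within model)
#'
#' Classic contrast `H = d' (V_FE - V_RE)^{-1} d` between the within (FE)
#' and Swamy-Arora GLS (RE) slope estimates of the non-spatial panel
#' regression, run before spatial estimation to choose the effects
#' specification. A non-positive-definite contrast covariance triggers a
#' pseudo-inverse fallback (flagged).
#'
#' @param data,response,regressors,unit,time as in [fit_sdm()].
#' @return list: `statistic`, `df`, `p`, `pseudo_inverse` flag, `b_fe`,
#'   `b_re`.
#' @export
hausman_test <- function(data, response, regressors, unit = "unit_id",
                         time = "year") {
  ids <- sort(unique(as.character(data[[unit]])))
  yrs <- sort(unique(data[[time]]))
  n <- length(ids); t <- length(yrs); k <- length(regressors)
  ord <- order(match(data[[time]], yrs), match(data[[unit]], ids))
  data <- data[ord, , drop = FALSE]
  y <- as.numeric(data[[response]])
  X <- as.matrix(data[regressors])
  # FE (within)
  yw <- demean_panel(y, n, t, "unit")
  Xw <- demean_panel(X, n, t, "unit")
  b_fe <- drop(qr.coef(qr(Xw), yw))
  rw <- yw - Xw %*% b_fe
  s2e <- sum(rw^2) / (n * t - n - k)
  V_fe <- s2e * solve(crossprod(Xw))
  # RE (Swamy-Arora quasi-demeaning)
  ybar <- as.numeric(tapply(y, rep(ids, t), mean)[ids])
  Xbar <- apply(X, 2, function(cx) tapply(cx, rep(ids, t), mean)[ids])
  Zb <- cbind(1, Xbar)
  rb <- ybar - Zb %*% qr.coef(qr(Zb), ybar)
  s21 <- max(t * sum(rb^2) / (n - k - 1), s2e + 1e-12)
  th <- 1 - sqrt(s2e / s21)
  yq <- y - th * rep(ybar, t)
  Xq <- X - th * Xbar[rep(seq_len(n), t), , drop = FALSE]
  cq <- 1 - th
  Zq <- cbind(cq, Xq)
  b_all <- drop(qr.coef(qr(Zq), yq))
  b_re <- b_all[-1]
  V_re_full <- s2e * solve(crossprod(Zq))
  V_re <- V_re_full[-1, -1, drop = FALSE]
  d <- b_fe - b_re
  V <- V_fe - V_re
  used_pinv <- FALSE
  Vi <- tryCatch({
    if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values <= 0))
      stop("not pd")
    solve(V)
  }, error = function(e) {
    used_pinv <<- TRUE
    MASS_ginv(V)
  })
  stat <- max(drop(t(d) %*% Vi %*% d), 0)
  list(statistic = stat, df = k, p = pchisq(stat, k, lower.tail = FALSE),
       pseudo_inverse = used_pinv, b_fe = b_fe, b_re = setNames(b_re,
                                                                regressors))
}

#' Variance inflation factors
#'
#' `VIF_k = 1/(1 - R2_k)` from regressing regressor k (with intercept) on
#' the remaining regressors. Perfect collinearity yields `Inf`.
#'
#' @param X numeric matrix or data.frame of regressors (>= 2 columns).
#' @return named numeric vector.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 regressors")
  nm <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  setNames(out, nm)
}
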