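# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# entropy-method formulas evaluated term by term with explicit loops
oracle_entropy_weights <- function(X) {
  m <- nrow(X); k <- ncol(X)
  P <- matrix(0, m, k)
  for (j in 1:k) for (i in 1:m) P[i, j] <- X[i, j] / sum(X[, j])
  e <- numeric(k)
  for (j in 1:k) {
    s <- 0
    for (i in 1:m) if (P[i, j] > 0) s <- s + P[i, j] * log(P[i, j])
    e[j] <- -s / log(m)
  }
  g <- 1 - e
  list(weights = g / sum(g), entropy = e)
}

# global Moran's I by direct double summation
oracle_moran <- function(x, Wm) {
  n <- length(x); xb <- mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n)
    num <- num + Wm[i, j] * (x[i] - xb) * (x[j] - xb)
  den <- (sum((x - xb)^2) / n) * sum(Wm)
  num / den
}

# dense-matrix impact decomposition for a small instance
oracle_impacts <- function(rho, beta_k, theta_k, Wm) {
  n <- nrow(Wm)
  S <- solve(diag(n) - rho * Wm) %*% (diag(beta_k, n) + Wm * theta_k)
  direct <- sum(diag(S)) / n
  total <- sum(S) / n
  c(direct = direct, indirect = total - direct, total = total)
}

# round-half-up at 3 decimals (printed-table convention)
round3 <- function(x) floor(x * 1000 + 0.5) / 1000

# shared synthetic geometry
lattice31 <- function() {
  co <- make_coordinates(31, "grid")
  grid_contiguity_weights(co, "row")
}
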