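#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Dense two-phase tableau simplex, specialised for the small envelopment LPs
// DEA generates (tens of rows, <100 columns). Dantzig pricing with a switch
// to Bland's rule after maxit/2 iterations to break degenerate cycling —
// input-oriented envelopment LPs have zero right-hand sides on every input
// row, so degeneracy is the norm, not the exception.
//
// Tableau layout: rows 0..m-1 constraints, row m reduced costs; the last
// column is the RHS; the RHS entry of the cost row holds -(objective).
// Entering columns are restricted to j < ncand so artificial columns can
// never re-enter in phase 2.
static int simplex_iterate(mat& T, ivec& basis, const int ncand,
                           const double tol, const int maxit) {
  const int m = T.n_rows - 1;
  const int rhs = T.n_cols - 1;
  bool bland = false;
  for (int it = 0; it < maxit; ++it) {
    if (it > maxit / 2) bland = true;
    int enter = -1;
    double best = -tol;
    for (int j = 0; j < ncand; ++j) {
      const double cj = T(m, j);
      if (cj < -tol) {
        if (bland) { enter = j; break; }
        if (cj < best) { best = cj; enter = j; }
      }
    }
    if (enter < 0) return 0;               // optimal
    int leave = -1;
    double bratio = datum::inf;
    for (int i = 0; i < m; ++i) {
      const double a = T(i, enter);
      if (a > tol) {
        const double ratio = T(i, rhs) / a;
        if (ratio < bratio - 1e-12 ||
            (std::abs(ratio - bratio) <= 1e-12 &&
             (leave < 0 || basis(i) < basis(leave)))) {
          bratio = ratio;
          leave = i;
        }
      }
    }
    if (leave < 0) return 1;               // unbounded
    T.row(leave) /= T(leave, enter);
    for (int i = 0; i <= m; ++i) {
      if (i == leave) continue;
      const double f = T(i, enter);
      if (f != 0.0) T.row(i) -= f * T.row(leave);
    }
    basis(leave) = enter;
  }
  return 2;                                // iteration limit
}

// Solve min c'x, A x = b (b >= 0), x >= 0. Returns 0/1/2/3 status
// (optimal / unbounded / maxit / infeasible); objective and primal solution
// written through the references.
static int lp_two_phase(const mat& A, const vec& b, const vec& c,
                        double& obj, vec& x, const double tol = 1e-9,
                        const int maxit = 20000) {
  const int m = A.n_rows, n = A.n_cols;
  mat T(m + 1, n + m + 1, fill::zeros);
  T.submat(0, 0, m - 1, n - 1) = A;
  T.submat(0, n, m - 1, n + m - 1) = eye(m, m);
  T.col(n + m).head(m) = b;
  ivec basis = regspace<ivec>(n, n + m - 1);
  // phase-1 reduced costs: 0 - sum of constraint rows (artificial costs = 1)
  for (int j = 0; j < n; ++j) T(m, j) = -accu(T.col(j).head(m));
  T(m, n + m) = -accu(b);
  int st = simplex_iterate(T, basis, n, tol, maxit);
  if (st != 0) return st;
  if (-T(m, n + m) > 1e-7) return 3;       // infeasible
  // drive any residual (degenerate) artificials out where possible
  for (int i = 0; i < m; ++i) {
    if (basis(i) >= n) {
      for (int j = 0; j < n; ++j) {
        if (std::abs(T(i, j)) > tol) {
          T.row(i) /= T(i, j);
          for (int k = 0; k <= m; ++k) {
            if (k == i) continue;
            const double f = T(k, j);
            if (f != 0.0) T.row(k) -= f * T.row(i);
          }
          basis(i) = j;
          break;
        }
      }
    }
  }
  // phase-2 cost row
  for (int j = 0; j < n + m; ++j) T(m, j) = (j < n) ? c(j) : 0.0;
  T(m, n + m) = 0.0;
  for (int i = 0; i < m; ++i) {
    if (basis(i) < n && c(basis(i)) != 0.0) T.row(m) -= c(basis(i)) * T.row(i);
  }
  st = simplex_iterate(T, basis, n, tol, maxit);
  if (st != 0) return st;
  obj = -T(m, n + m);
  x.zeros(n);
  for (int i = 0; i < m; ++i)
    if (basis(i) < n) x(basis(i)) = T(i, n + m);
  return 0;
}

//' @noRd
// [[Rcpp::export(name = ".dea_scores_cpp")]]
arma::vec dea_scores_cpp(const arma::mat& Xref, const arma::mat& Yref,
                         const arma::mat& Xev, const arma::mat& Yev,
                         const bool vrs) {
  const int n = Xref.n_rows, p = Xref.n_cols, q = Yref.n_cols;
  const int ne = Xev.n_rows;
  const int m = p + q + (vrs ? 1 : 0);
  const int nv = 1 + n + p + q;            // theta, lambda, input/output slacks
  vec theta(ne);
  mat A(m, nv);
  vec b(m), c(nv, fill::zeros), x;
  c(0) = 1.0;
  // rows 0..p-1:   theta*x_e - X'lambda - s = 0
  // rows p..p+q-1: Y'lambda - t = y_e
  // row p+q (VRS): 1'lambda = 1
  for (int e = 0; e < ne; ++e) {
    A.zeros();
    b.zeros();
    for (int k = 0; k < p; ++k) {
      A(k, 0) = Xev(e, k);
      for (int j = 0; j < n; ++j) A(k, 1 + j) = -Xref(j, k);
      A(k, 1 + n + k) = -1.0;
    }
    for (int l = 0; l < q; ++l) {
      for (int j = 0; j < n; ++j) A(p + l, 1 + j) = Yref(j, l);
      A(p + l, 1 + n + p + l) = -1.0;
      b(p + l) = Yev(e, l);
    }
    if (vrs) {
      for (int j = 0; j < n; ++j) A(p + q, 1 + j) = 1.0;
      b(p + q) = 1.0;
    }
    double obj = datum::nan;
    const int st = lp_two_phase(A, b, c, obj, x);
    if (st == 3) {
      theta(e) = datum::nan;               // infeasible (possible under VRS
    } else if (st != 0) {                  //  when evaluating outside units)
      Rcpp::stop("LP solver failed (status %d) for DMU %d", st, e + 1);
    } else {
      theta(e) = obj;
    }
  }
  return theta;
}
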