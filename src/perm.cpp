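// Hot loop of the permutation test: the genetic-block quadratic form
// d' Sigma^+ d / q_phi recomputed for every permuted genotype assignment.
// Mirrors the R reference path (genetic_term / pinv_quad) exactly: pooled
// two-group covariance with divisor n - 2 and an eigenvalue-truncated
// pseudo-inverse with relative cutoff `tol`.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double pinv_quad_cpp(const mat& S, const vec& d, double tol) {
  if (d.n_elem == 0) return 0.0;
  vec eval;
  mat evec;
  eig_sym(eval, evec, S);
  double emax = eval.max();
  if (emax <= 0) return 0.0;
  vec y = evec.t() * d;
  double q = 0.0;
  for (uword k = 0; k < eval.n_elem; ++k)
    if (eval(k) > tol * emax) q += y(k) * y(k) / eval(k);
  return q;
}

// X: n x p genotype block [Z | V] (constant columns already dropped),
// cases-first contract irrelevant here: `perms` (L x n, 1-based) gives the
// permuted order, of which the first nc entries are the case rows.
// [[Rcpp::export]]
Rcpp::NumericVector perm_genetic_stats(const arma::mat& X,
                                       const arma::umat& perms,
                                       const int nc, const int n_z,
                                       const double q_phi, const bool split,
                                       const double tol) {
  const uword n = X.n_rows, p = X.n_cols, L = perms.n_rows;
  const uword nd = n - nc;
  Rcpp::NumericVector out(L);
  if (p == 0) return out;
  const mat Ctot = X.t() * X;
  const rowvec Stot = sum(X, 0);
  for (uword l = 0; l < L; ++l) {
    uvec idx = perms.row(l).head(nc).t() - 1;
    mat Xc = X.rows(idx);
    mat Cc = Xc.t() * Xc;
    rowvec Sc = sum(Xc, 0);
    vec mc = Sc.t() / nc;
    vec md = (Stot - Sc).t() / nd;
    mat scatter = (Cc - double(nc) * mc * mc.t()) +
                  ((Ctot - Cc) - double(nd) * md * md.t());
    mat sig = scatter / double(n - 2);
    vec d = (double(nc) * nd / n) * (mc - md);
    double num;
    if (split) {
      num = 0.0;
      if (n_z > 0)
        num += pinv_quad_cpp(sig.submat(0, 0, n_z - 1, n_z - 1),
                             d.head(n_z), tol);
      if (p > (uword)n_z)
        num += pinv_quad_cpp(sig.submat(n_z, n_z, p - 1, p - 1),
                             d.tail(p - n_z), tol);
    } else {
      num = pinv_quad_cpp(sig, d, tol);
    }
    out[l] = num / q_phi;
  }
  return out;
}
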