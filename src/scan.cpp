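// Fast per-SNP logistic fits for the ROH-status association scan.
// Each SNP adds up to three columns (ROH+hom-minor indicator, ROH+hom-major
// indicator, additive dosage) to a shared base design; IRLS is warm-started
// from the base-model fit.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List logistic_scan_cpp(const arma::mat& Xbase,
                       const arma::vec& y,
                       const arma::vec& beta_warm,
                       const IntegerMatrix& roh_state, // n x m: 0/1/2
                       const NumericMatrix& dosage,    // n x m, imputed
                       int maxit = 30,
                       double tol = 1e-8) {
  const int n = Xbase.n_rows, p0 = Xbase.n_cols, m = roh_state.ncol();
  NumericVector beta_a(m, NA_REAL), se_a(m, NA_REAL);
  NumericVector beta_b(m, NA_REAL), se_b(m, NA_REAL);
  NumericVector beta_add(m, NA_REAL), se_add(m, NA_REAL);
  IntegerVector n_a(m), n_b(m);
  LogicalVector converged(m);

  arma::mat X(n, p0 + 3);
  X.cols(0, p0 - 1) = Xbase;

  for (int j = 0; j < m; ++j) {
    arma::vec a(n), b(n), d(n);
    int na = 0, nb = 0;
    for (int i = 0; i < n; ++i) {
      int s = roh_state(i, j);
      a[i] = (s == 1) ? 1.0 : 0.0;
      b[i] = (s == 2) ? 1.0 : 0.0;
      d[i] = dosage(i, j);
      na += (s == 1);
      nb += (s == 2);
    }
    n_a[j] = na;
    n_b[j] = nb;
    bool use_a = na > 0 && na < n;
    bool use_b = nb > 0 && nb < n;
    bool use_d = arma::var(d) > 0;

    // active columns: base + selected SNP columns
    int p = p0 + use_a + use_b + use_d;
    int col = p0;
    int ia = -1, ib = -1, id = -1;
    if (use_a) { X.col(col) = a; ia = col++; }
    if (use_b) { X.col(col) = b; ib = col++; }
    if (use_d) { X.col(col) = d; id = col++; }
    arma::mat Xa = X.cols(0, p - 1);

    arma::vec beta(p, arma::fill::zeros);
    beta.head(p0) = beta_warm;
    bool ok = false;
    arma::mat XtWX(p, p);
    for (int it = 0; it < maxit; ++it) {
      arma::vec eta = Xa * beta;
      eta = arma::clamp(eta, -30.0, 30.0);
      arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
      arma::vec w = mu % (1.0 - mu) + 1e-12;
      arma::vec z = eta + (y - mu) / w;
      arma::mat Xw = Xa.each_col() % w;
      XtWX = Xa.t() * Xw;
      arma::vec XtWz = Xw.t() * z;
      arma::vec beta_new;
      bool solved = arma::solve(beta_new, XtWX, XtWz,
                                arma::solve_opts::likely_sympd);
      if (!solved) { ok = false; break; }
      double delta = arma::abs(beta_new - beta).max();
      beta = beta_new;
      if (delta < tol) { ok = true; break; }
    }
    if (ok && arma::abs(beta).max() > 15.0) ok = false; // separation guard
    converged[j] = ok;
    if (!ok) continue;

    arma::mat V;
    if (!arma::inv_sympd(V, XtWX)) { converged[j] = false; continue; }
    if (ia >= 0) { beta_a[j] = beta[ia]; se_a[j] = std::sqrt(V(ia, ia)); }
    if (ib >= 0) { beta_b[j] = beta[ib]; se_b[j] = std::sqrt(V(ib, ib)); }
    if (id >= 0) { beta_add[j] = beta[id]; se_add[j] = std::sqrt(V(id, id)); }
  }
  return List::create(
    _["beta_a"] = beta_a, _["se_a"] = se_a,
    _["beta_b"] = beta_b, _["se_b"] = se_b,
    _["beta_add"] = beta_add, _["se_add"] = se_add,
    _["n_a"] = n_a, _["n_b"] = n_b, _["converged"] = converged);
}
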