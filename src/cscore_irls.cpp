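// IRLS moment estimation under the Poisson measurement model.
// Mirrors the reference R implementation (.cscore_irls_r) exactly; the two
// are asserted equal in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".cscore_irls_cpp")]]
Rcpp::List cscore_irls_cpp(const arma::mat& X, const arma::vec& s,
                           int max_iter, double tol) {
  const uword p = X.n_cols;
  vec s2 = square(s);
  vec s4 = square(s2);
  rowvec mu = sum(X, 0) / accu(s);
  uvec zero = find(mu <= 0);
  mu.elem(zero).zeros();
  mat M = s * mu;
  mat E = X - M;
  mat E2M = square(E) - M;
  rowvec sig = sum(E2M.each_col() % s2, 0) / accu(s4);
  sig.clamp(0.0, datum::inf);
  sig.elem(zero).zeros();
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    mat V = M + s2 * sig;
    for (uword k = 0; k < zero.n_elem; ++k) V.col(zero(k)).ones();
    mat W = 1.0 / V;
    mat Ws = W.each_col() % s;
    rowvec mu_new = sum(Ws % X, 0) / sum(Ws.each_col() % s, 0);
    mu_new.elem(zero).zeros();
    M = s * mu_new;
    E = X - M;
    mat W2 = square(W);
    mat R2 = W2 % (square(E) - M);
    rowvec sig_new = sum(R2.each_col() % s2, 0) / sum(W2.each_col() % s4, 0);
    sig_new.clamp(0.0, datum::inf);
    sig_new.elem(zero).zeros();
    double delta = std::max(abs(mu_new - mu).max(), abs(sig_new - sig).max());
    mu = mu_new;
    sig = sig_new;
    if (delta < tol) {
      converged = true;
      break;
    }
  }
  if (it > max_iter) it = max_iter;
  mat V = M + s2 * sig;
  for (uword k = 0; k < zero.n_elem; ++k) V.col(zero(k)).ones();
  mat W = 1.0 / V;
  mat WE = W % E;
  mat B = WE.each_col() % s;
  mat C = W.each_col() % s2;
  Rcpp::LogicalVector zmask(p, false);
  for (uword k = 0; k < zero.n_elem; ++k) zmask[zero(k)] = true;
  return Rcpp::List::create(
      Rcpp::Named("mu") = Rcpp::NumericVector(mu.begin(), mu.end()),
      Rcpp::Named("sig") = Rcpp::NumericVector(sig.begin(), sig.end()),
      Rcpp::Named("num") = B.t() * B,
      Rcpp::Named("den") = C.t() * C,
      Rcpp::Named("n_iter") = it,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("zero") = zmask);
}
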