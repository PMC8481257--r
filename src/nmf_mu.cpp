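#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF for the Frobenius objective ||D - PT||^2.
// P and T stay elementwise non-negative; the error is non-increasing over
// iterations (Lee-Seung updates). The squared error is evaluated every
// `check_every` iterations and iteration stops when its relative change
// falls below `tol` or after `max_iter` iterations.
// [[Rcpp::export(name = ".nmf_mu")]]
Rcpp::List nmf_mu(const arma::mat& D, arma::mat P, arma::mat T,
                  int max_iter, double tol, int check_every) {
  const double eps = 1e-12;
  std::vector<double> err_trace;
  double err_prev = datum::inf;
  double err = datum::inf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // T <- T * (P'D) / (P'P T)
    mat PtD = P.t() * D;
    mat PtPT = (P.t() * P) * T;
    T %= PtD / (PtPT + eps);
    // P <- P * (D T') / (P T T')
    mat DTt = D * T.t();
    mat PTTt = P * (T * T.t());
    P %= DTt / (PTTt + eps);
    if (it % check_every == 0 || it == max_iter) {
      err = accu(square(D - P * T));
      err_trace.push_back(err);
      if (std::isfinite(err_prev) &&
          std::abs(err_prev - err) <= tol * std::max(err_prev, eps)) {
        break;
      }
      err_prev = err;
    }
  }
  if (!std::isfinite(err)) {
    err = accu(square(D - P * T));
    err_trace.push_back(err);
  }
  return Rcpp::List::create(
      Rcpp::Named("P") = P, Rcpp::Named("T") = T,
      Rcpp::Named("error") = err,
      Rcpp::Named("error_trace") = err_trace,
      Rcpp::Named("iterations") = std::min(it, max_iter));
}
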