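#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Multiplicative-update NMF (Frobenius objective). Factors are floored at
// 1e-12 so entries never get absorbed at exact zero, which would freeze them
// under multiplicative updates. Stops when the relative decrease of
// ||V - WH||^2_F between iterations falls below tol.
// [[Rcpp::export(name = ".nnmf_mu")]]
List nnmf_mu(const arma::mat& V, arma::mat W, arma::mat H,
             int max_iter, double tol, bool trace) {
  const double floor_val = 1e-12;
  const double eps = 1e-12;
  std::vector<double> objective;
  if (trace) objective.reserve(max_iter);
  double prev = arma::datum::inf;
  double f = arma::accu(arma::square(V - W * H));
  int it = 0;
  bool converged = false;
  for (it = 0; it < max_iter; ++it) {
    H %= (W.t() * V) / (W.t() * W * H + eps);
    H.transform([&](double x) { return x < floor_val ? floor_val : x; });
    W %= (V * H.t()) / (W * H * H.t() + eps);
    W.transform([&](double x) { return x < floor_val ? floor_val : x; });
    prev = f;
    f = arma::accu(arma::square(V - W * H));
    if (trace) objective.push_back(f);
    if (prev > 0 && (prev - f) / prev < tol) { converged = true; ++it; break; }
  }
  return List::create(_["W"] = W, _["H"] = H, _["objective"] = f,
                      _["iterations"] = it, _["converged"] = converged,
                      _["trace"] = objective);
}
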