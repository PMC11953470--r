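// Multiplicative-update NMF with the Kullback-Leibler objective.
// Initial factors are generated in R so all randomness stays under R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static double kl_obj(const arma::mat& V, const arma::mat& WH, double eps) {
  double obj = 0.0;
  const arma::uword n = V.n_elem;
  for (arma::uword i = 0; i < n; ++i) {
    const double v = V(i);
    const double wh = WH(i) + eps;
    if (v > 0.0) obj += v * std::log(v / wh) - v;
    obj += wh;
  }
  return obj;
}

// [[Rcpp::export(name = ".nmf_kl_fit")]]
Rcpp::List nmf_kl_fit(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, double eps = 1e-12) {
  double obj_prev = std::numeric_limits<double>::infinity();
  int it_done = max_iter;
  arma::mat Q;
  for (int it = 1; it <= max_iter; ++it) {
    // H update: H *= (W' (V/WH)) / colsum(W)
    Q = V / (W * H + eps);
    H %= W.t() * Q;
    H.each_col() /= arma::vec(arma::sum(W, 0).t() + eps);
    // W update: W *= ((V/WH) H') / rowsum(H)
    Q = V / (W * H + eps);
    W %= Q * H.t();
    W.each_row() /= arma::rowvec(arma::sum(H, 1).t() + eps);

    if (it % 10 == 0 || it == max_iter) {
      double obj = kl_obj(V, W * H, eps);
      if (std::isfinite(obj_prev) &&
          std::fabs(obj_prev - obj) <= tol * std::max(std::fabs(obj_prev), 1.0)) {
        it_done = it;
        break;
      }
      obj_prev = obj;
    }
  }
  double obj = kl_obj(V, W * H, eps);
  return Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("iterations") = it_done);
}
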