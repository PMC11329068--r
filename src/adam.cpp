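#include <Rcpp.h>

// In-place Adam update over a named list of parameter arrays.
// The caller owns `params`, `m` and `v` exclusively (freshly allocated at
// the start of training), so mutating them here is safe and avoids
// re-allocating tens of megabytes of parameter copies every step.
// [[Rcpp::export]]
void adam_update_(Rcpp::List params, Rcpp::List m, Rcpp::List v,
                  Rcpp::List grads, double lr, double b1, double b2,
                  double eps, int t) {
  const double bc1 = 1.0 - std::pow(b1, t);
  const double bc2 = 1.0 - std::pow(b2, t);
  Rcpp::CharacterVector nms = params.names();
  for (int k = 0; k < params.size(); ++k) {
    std::string nm = Rcpp::as<std::string>(nms[k]);
    Rcpp::NumericVector p = params[k];
    Rcpp::NumericVector mk = m[k];
    Rcpp::NumericVector vk = v[k];
    Rcpp::NumericVector g = grads[nm];
    const R_xlen_t n = p.size();
    if (mk.size() != n || vk.size() != n || g.size() != n) {
      Rcpp::stop("adam_update_: size mismatch for parameter '%s'", nm.c_str());
    }
    double *pp = p.begin(), *pm = mk.begin(), *pv = vk.begin(), *pg = g.begin();
    for (R_xlen_t i = 0; i < n; ++i) {
      pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
      pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
      pp[i] -= lr * (pm[i] / bc1) / (std::sqrt(pv[i] / bc2) + eps);
    }
  }
}
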