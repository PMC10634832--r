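#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of observed choices under the feature-value RL
// model. Feature levels are indexed 0..5 (c1, c2, up, down, left, right);
// `chosen` / `unchosen` hold the 0-based level indices per trial (n x 3).
// Values reset to v0 wherever `new_session` is true.
// [[Rcpp::export]]
double rl_negloglik_cpp(const IntegerMatrix& chosen,
                        const IntegerMatrix& unchosen,
                        const IntegerVector& outcome,
                        const LogicalVector& new_session,
                        const NumericVector& weights,
                        double eta, double beta, double gamma, double v0) {
  const int n = chosen.nrow();
  double v[6];
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (new_session[t]) {
      for (int k = 0; k < 6; ++k) v[k] = v0;
    }
    double vc = 0.0, vu = 0.0;
    for (int d = 0; d < 3; ++d) {
      vc += weights[d] * v[chosen(t, d)];
      vu += weights[d] * v[unchosen(t, d)];
    }
    // log P(chosen) = -log(1 + exp(-beta (vc - vu))), numerically stable
    const double z = beta * (vc - vu);
    nll += (z > 0) ? std::log1p(std::exp(-z)) : (std::log1p(std::exp(z)) - z);
    const double delta = outcome[t] - vc;
    for (int d = 0; d < 3; ++d) {
      v[chosen(t, d)] += eta * delta;
      v[unchosen(t, d)] += gamma * (v0 - v[unchosen(t, d)]);
    }
  }
  return nll;
}
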