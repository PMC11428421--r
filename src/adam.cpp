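// In-place Adam update with L2 weight decay folded into the gradient,
// fused into one pass to avoid R-level temporaries. The caller owns the
// only live references to p/m/v (training state), so in-place mutation is
// safe there.
#include <Rcpp.h>
#include <cmath>

// [[Rcpp::export(name = ".adam_step")]]
void adam_step(Rcpp::NumericMatrix p, Rcpp::NumericMatrix m,
               Rcpp::NumericMatrix v, Rcpp::NumericMatrix g,
               double lr, double beta1, double beta2, double eps,
               int step, double weight_decay) {
  R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    Rcpp::stop("shape mismatch in adam_step");
  double *pp = p.begin(), *pm = m.begin(), *pv = v.begin(), *pg = g.begin();
  const double ic1 = 1.0 / (1.0 - std::pow(beta1, step));
  const double ic2 = 1.0 / (1.0 - std::pow(beta2, step));
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = pg[i] + weight_decay * pp[i];
    double mi = beta1 * pm[i] + om1 * gi;
    double vi = beta2 * pv[i] + om2 * gi * gi;
    pm[i] = mi;
    pv[i] = vi;
    pp[i] -= lr * mi * ic1 / (std::sqrt(vi * ic2) + eps);
  }
}
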