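#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential replay of one session under a given parameter setting.
// Cues are coded 1..4 (SURE0, SURE5, SURE10, RISKY); cue_b == 0 on forced
// trials. Models: 1 asymmetric, 2 classical, 3 nonlinear utility, 4 WSLS
// (classical with learning rate 1). Values start at 0; choice trials add
// -log p(chosen) with p floored at 1e-12; forced trials only drive learning.

// [[Rcpp::export]]
double replay_negloglik_cpp(IntegerVector cue_a, IntegerVector cue_b,
                            LogicalVector is_choice, IntegerVector chosen,
                            NumericVector reward, LogicalVector aborted,
                            int model, double eta, double kappa,
                            double beta, double a) {
  const int n = cue_a.size();
  double V[5] = {0.0, 0.0, 0.0, 0.0, 0.0};
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (aborted[t]) continue;
    const int ch = chosen[t];
    if (is_choice[t]) {
      const int other = (ch == cue_a[t]) ? cue_b[t] : cue_a[t];
      const double x = beta * (V[ch] - V[other]);
      double p = (x >= 0.0) ? 1.0 / (1.0 + std::exp(-x))
                            : std::exp(x) / (1.0 + std::exp(x));
      if (p < 1e-12) p = 1e-12;
      nll -= std::log(p);
    }
    double r = reward[t];
    if (model == 3 && r == 10.0) r = 10.0 * a;  // U(0)=0, U(5)=5, U(10)=10a
    const double delta = r - V[ch];
    double fac = 1.0;
    if (model == 1)
      fac = (delta > 0.0) ? (1.0 + kappa) : ((delta < 0.0) ? (1.0 - kappa) : 1.0);
    const double lr = (model == 4) ? 1.0 : eta;
    V[ch] += lr * delta * fac;
  }
  return nll;
}
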