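#include <Rcpp.h>
using namespace Rcpp;

// Event-driven between-spike recursion for the Tsodyks-Markram model family.
// State convention: (R_1, u_1) = (1, U); release at spike n uses the pre-jump
// u_n, so the facilitation increment f(1 - u) influences spike n+1 onward.
// variant: 0 = eTM (4 params), 1 = TM with facilitation (caller ties f = U),
// 2 = TM depression-only (u pinned at U).
// [[Rcpp::export(name = ".psp_recursion")]]
NumericVector psp_recursion(NumericVector times, double D, double F,
                            double U, double f, int variant) {
  int n = times.size();
  NumericVector amps(n);
  double R = 1.0, u = U;
  for (int i = 0; i < n; ++i) {
    amps[i] = R * u;
    if (i + 1 < n) {
      double dt = times[i + 1] - times[i];
      double eD = std::exp(-dt / D);
      R = 1.0 - (1.0 - R * (1.0 - u)) * eD;
      if (variant != 2) {
        double eF = std::exp(-dt / F);
        u = U + (u + f * (1.0 - u) - U) * eF;
      }
    }
  }
  return amps;
}
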