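#include <Rcpp.h>
using namespace Rcpp;

// Sum of squared residuals for a labelled A/Ci curve under the coupled
// biochemical model. theta = (Vcmax, Jmax, TPU, Rd, rm); state codes:
// 0 rubisco, 1 rubp, 2 tpu. Infeasible points (negative discriminant or
// Cc <= 0) incur the same penalty as the R reference objective. This is the
// optimizer's inner loop only; the R forward model is the reference path.
// [[Rcpp::export(name = ".fvcb_sse_kernel")]]
double fvcb_sse_kernel(NumericVector theta, NumericVector ci,
                       NumericVector aobs, IntegerVector state,
                       double km, double gamma_star) {
  const double vcmax = theta[0], jmax = theta[1], tpu = theta[2],
               rd = theta[3], rm = theta[4];
  const int n = ci.size();
  double sse = 0.0;
  int nbad = 0;
  for (int i = 0; i < n; ++i) {
    double a;
    if (state[i] == 2) {
      a = 3.0 * tpu - rd;
    } else {
      const double p = (state[i] == 0) ? vcmax : jmax / 4.0;
      const double q = (state[i] == 0) ? km : 2.0 * gamma_star;
      const double cc_term = ci[i] + q;
      const double cst = p * (ci[i] - gamma_star) - rd * cc_term;
      if (rm == 0.0) {
        a = cst / cc_term;
      } else {
        const double b = cc_term + rm * (p - rd);
        const double disc = b * b - 4.0 * rm * cst;
        if (disc < 0.0) { ++nbad; continue; }
        a = (b - std::sqrt(disc)) / (2.0 * rm);
      }
    }
    const double cc = ci[i] - rm * a;
    if (cc <= 0.0) { ++nbad; continue; }
    const double r = aobs[i] - a;
    sse += r * r;
  }
  if (nbad > 0) return 1e8 + 1e6 * nbad;
  return sse;
}
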