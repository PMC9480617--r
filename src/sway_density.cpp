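#include <Rcpp.h>
using namespace Rcpp;

// Number of consecutive samples around each sample t (in both directions,
// including t itself) whose planar distance to CoP(t) is at most `radius`.
// Expansion stops at the first sample leaving the disc, so the scan is
// O(n * mean run length).
// [[Rcpp::export]]
IntegerVector sway_density_counts(NumericVector ml, NumericVector ap,
                                  double radius) {
  const int n = ml.size();
  const double r2 = radius * radius;
  IntegerVector out(n);
  for (int t = 0; t < n; ++t) {
    int count = 1;
    for (int k = t - 1; k >= 0; --k) {
      const double dx = ml[k] - ml[t], dy = ap[k] - ap[t];
      if (dx * dx + dy * dy <= r2) ++count; else break;
    }
    for (int k = t + 1; k < n; ++k) {
      const double dx = ml[k] - ml[t], dy = ap[k] - ap[t];
      if (dx * dx + dy * dy <= r2) ++count; else break;
    }
    out[t] = count;
  }
  return out;
}
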