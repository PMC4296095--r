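#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy.
// B = pairs of length-m templates within Chebyshev distance r,
// A = same for length m+1; self-matches excluded (i < j only).
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  double A = 0.0, B = 0.0;
  // pairs (i, j), i < j, both templates fully inside the series
  for (int i = 0; i + m < n; ++i) {
    for (int j = i + 1; j + m < n; ++j) {
      double dmax = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double d = std::fabs(x[i + m] - x[j + m]);
      if (d > dmax) dmax = d;
      if (dmax <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
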