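#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman convention):
// templates x[i..i+m-1] for i = 0..N-m-1 where N = n, i.e. the same n-m
// template start positions are used for lengths m and m+1; a pair (i, j),
// i < j, matches when the Chebyshev distance is <= r; self-matches are
// excluded. Returns c(A, B): A = matches at length m+1, B at length m.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m; // number of template start positions
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::abs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (ok) {
        B += 1.0;
        double dd = std::abs(x[i + m] - x[j + m]);
        if (dd <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
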