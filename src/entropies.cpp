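#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Approximate entropy (Chebyshev distance, self-matches included):
// phi^m(r) = mean_i ln( C_i^m / (N - m + 1) ), ApEn = phi^m - phi^{m+1}.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  auto phi = [&](int mm) {
    int n = N - mm + 1;
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      int cnt = 0;
      for (int j = 0; j < n; ++j) {
        double d = 0.0;
        bool ok = true;
        for (int k = 0; k < mm; ++k) {
          double ad = std::fabs(x[i + k] - x[j + k]);
          if (ad > d) d = ad;
          if (d > r) { ok = false; break; }
        }
        if (ok) ++cnt;
      }
      s += std::log((double)cnt / (double)n);
    }
    return s / (double)n;
  };
  return phi(m) - phi(m + 1);
}

// Sample entropy match counts (Chebyshev distance, self-matches excluded):
// B = # pairs i<j (templates of length m), A = same for length m+1, with
// both template sets restricted to i,j in 1..N-m so every length-m template
// has a length-(m+1) continuation.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  int n = N - m;  // usable templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double ad = std::fabs(x[i + k] - x[j + k]);
        if (ad > d) d = ad;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
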