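#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-matching counts for sample entropy (Richman-Moorman convention):
// templates i < j, both drawn from the n - m windows that can be extended to
// length m + 1; Chebyshev distance; self-matches excluded by i < j.
// Returns c(A, B): matches at length m + 1 and at length m.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m;  // extendable templates
  const double *p = REAL(x);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < N - 1; ++i) {
    const double *pi = p + i;
    for (int j = i + 1; j < N; ++j) {
      const double *pj = p + j;
      double d = 0.0;
      int k = 0;
      for (; k < m; ++k) {
        double t = std::fabs(pi[k] - pj[k]);
        if (t > d) {
          d = t;
          if (d > r) break;
        }
      }
      if (k == m && d <= r) {
        B += 1.0;
        double t = std::fabs(pi[m] - pj[m]);
        if (t <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Pincus phi_m: mean over templates of log(C_i / N_m) with self-inclusive
// match counts C_i over the N_m = n - m + 1 length-m templates.
// [[Rcpp::export]]
double apen_phi(NumericVector x, int m, double r) {
  const int n = x.size();
  const int N = n - m + 1;
  const double *p = REAL(x);
  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    const double *pi = p + i;
    int c = 0;
    for (int j = 0; j < N; ++j) {
      const double *pj = p + j;
      int k = 0;
      for (; k < m; ++k) {
        double t = std::fabs(pi[k] - pj[k]);
        if (t > r) break;
      }
      if (k == m) ++c;
    }
    s += std::log((double)c / N);
  }
  return s / N;
}
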