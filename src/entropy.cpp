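#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev template-match counting for approximate and sample entropy.
// Returns, for each tolerance r: per-template match counts for length-m
// and length-(m+1) templates (self-matches included, as ApEn requires),
// and the SampEn pair totals A and B (self-matches excluded, templates
// restricted to i, j <= n - m).
// [[Rcpp::export(name = ".cheb_counts")]]
List cheb_counts(NumericVector x, int m, NumericVector r_vec) {
  const int n = x.size();
  const int nm = n - m;                 // number of (m+1)-templates
  const int nr = r_vec.size();
  NumericMatrix phi_m(nm + 1, nr);      // m-template counts, i = 0..n-m
  NumericMatrix phi_m1(nm, nr);
  NumericVector A(nr), B(nr);

  for (int i = 0; i <= nm; ++i) {
    for (int j = 0; j <= nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(x[i + k] - x[j + k]);
        if (a > d) d = a;
      }
      double d3 = d;
      bool have3 = (i < nm && j < nm);
      if (have3) {
        double a = std::fabs(x[i + m] - x[j + m]);
        if (a > d3) d3 = a;
      }
      for (int ri = 0; ri < nr; ++ri) {
        if (d <= r_vec[ri]) {
          phi_m(i, ri) += 1.0;
          if (have3 && i != j) B[ri] += 1.0;
        }
        if (have3 && d3 <= r_vec[ri]) {
          phi_m1(i, ri) += 1.0;
          if (i != j) A[ri] += 1.0;
        }
      }
    }
  }
  return List::create(_["phi_m"] = phi_m, _["phi_m1"] = phi_m1,
                      _["A"] = A, _["B"] = B);
}
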