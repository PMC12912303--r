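// IIR filtering in direct form II transposed with explicit initial state,
// the building block for zero-phase (forward-backward) filtering with
// transient-free edges.

#include <Rcpp.h>

// [[Rcpp::export]]
Rcpp::NumericVector lfilter_df2t(const Rcpp::NumericVector& b,
                                 const Rcpp::NumericVector& a,
                                 const Rcpp::NumericVector& x,
                                 const Rcpp::NumericVector& zi) {
  const int n = std::max(b.size(), a.size());
  std::vector<double> bb(n, 0.0), aa(n, 0.0), z(n - 1, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  for (int i = 0; i < n; ++i) { bb[i] /= aa[0]; }
  for (int i = n - 1; i >= 0; --i) aa[i] /= aa[0];
  for (int i = 0; i < zi.size() && i < n - 1; ++i) z[i] = zi[i];
  Rcpp::NumericVector y(x.size());
  for (int t = 0; t < x.size(); ++t) {
    double yt = bb[0] * x[t] + z[0];
    for (int i = 0; i < n - 2; ++i)
      z[i] = bb[i + 1] * x[t] + z[i + 1] - aa[i + 1] * yt;
    z[n - 2] = bb[n - 1] * x[t] - aa[n - 1] * yt;
    y[t] = yt;
  }
  return y;
}
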