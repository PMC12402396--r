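#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter, zero initial state.
// a[0] is assumed normalised to 1 by the caller.
// [[Rcpp::export(name = ".iirFilter")]]
NumericVector iir_filter(NumericVector b, NumericVector a, NumericVector x) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int ns = std::max(nb, na) - 1;
  std::vector<double> z(ns, 0.0), bb(ns + 1, 0.0), aa(ns + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + z[0];
    for (int j = 0; j < ns - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    z[ns - 1] = bb[ns] * xi - aa[ns] * yi;
    y[i] = yi;
  }
  return y;
}
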