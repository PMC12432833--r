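#include <Rcpp.h>
using namespace Rcpp;

// Cascade of second-order IIR sections, direct form II transposed.
// Each row of `sos` is (b0, b1, b2, a1, a2) with a0 normalised to 1;
// first-order sections are padded with zeros.
// [[Rcpp::export]]
NumericVector sos_filter_cpp(NumericMatrix sos, NumericVector x) {
  int n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < sos.nrow(); ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 3), a2 = sos(s, 4);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
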