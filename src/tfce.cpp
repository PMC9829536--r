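#include <Rcpp.h>
using namespace Rcpp;

// One-sided 1-D TFCE on the positive part of x.
// enhanced(t) = sum over thresholds h = dh, 2dh, ... <= x(t) of
//   extent(t, h)^E * h^H * dh,
// where extent(t, h) is the length (in samples) of the contiguous
// suprathreshold run containing t at threshold h.
// [[Rcpp::export(name = ".tfce1d_pos")]]
NumericVector tfce1d_pos(NumericVector x, double E, double H, double dh) {
  const int n = x.size();
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (x[i] > mx) mx = x[i];
  if (mx <= 0.0 || dh <= 0.0) return out;
  const int nsteps = (int)std::floor(mx / dh + 1e-9);
  for (int s = 1; s <= nsteps; ++s) {
    const double h = s * dh;
    const double hH = std::pow(h, H) * dh;
    int i = 0;
    while (i < n) {
      if (x[i] >= h) {
        int j = i;
        while (j < n && x[j] >= h) ++j;
        const double contrib = std::pow((double)(j - i), E) * hH;
        for (int k = i; k < j; ++k) out[k] += contrib;
        i = j;
      } else {
        ++i;
      }
    }
  }
  return out;
}
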