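// Bilinear image resize with half-pixel-centred coordinates.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix x, int out_rows, int out_cols) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(out_rows, out_cols);
  double sr = (double)H / out_rows, sc = (double)W / out_cols;
  for (int j = 0; j < out_cols; ++j) {
    double yc = (j + 0.5) * sc - 0.5;
    int j0 = (int)std::floor(yc);
    double fy = yc - j0;
    int j1 = j0 + 1;
    if (j0 < 0) { j0 = 0; j1 = 0; fy = 0.0; }
    if (j1 >= W) { j1 = W - 1; if (j0 >= W) j0 = W - 1; }
    for (int i = 0; i < out_rows; ++i) {
      double xc = (i + 0.5) * sr - 0.5;
      int i0 = (int)std::floor(xc);
      double fx = xc - i0;
      int i1 = i0 + 1;
      if (i0 < 0) { i0 = 0; i1 = 0; fx = 0.0; }
      if (i1 >= H) { i1 = H - 1; if (i0 >= H) i0 = H - 1; }
      out(i, j) = (1 - fx) * (1 - fy) * x(i0, j0) + fx * (1 - fy) * x(i1, j0)
                + (1 - fx) * fy * x(i0, j1) + fx * fy * x(i1, j1);
    }
  }
  return out;
}
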