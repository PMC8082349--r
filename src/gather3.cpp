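// Hot loops of the 3D convolution lowering.  Batched feature maps are
// column-major matrices with rows = spatial positions stacked by batch
// sample and columns = channels (see nn.R).  Both gathers copy
// x-contiguous runs, so the inner loop is std::copy.

#include <Rcpp.h>
using namespace Rcpp;

// im2col for a valid 3x3x3 convolution over a batched feature matrix.
// x: (prod(sdim)*B) x cin; returns (prod(sdim-2)*B) x (27*cin) with
// channel-fastest columns within each kernel offset j = oz*9+oy*3+ox.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(const NumericMatrix& x, IntegerVector sdim,
                          int B) {
  const int d1 = sdim[0], d2 = sdim[1], d3 = sdim[2];
  const int o1 = d1 - 2, o2 = d2 - 2, o3 = d3 - 2;
  const int cin = x.ncol();
  const R_xlen_t npos = (R_xlen_t)d1 * d2 * d3;
  const R_xlen_t onpos = (R_xlen_t)o1 * o2 * o3;
  NumericMatrix col(onpos * B, 27 * cin);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int j = 0; j < 27; ++j) {
    const int ox = j % 3, oy = (j / 3) % 3, oz = j / 9;
    for (int c = 0; c < cin; ++c) {
      double* dst0 = cp + (R_xlen_t)(j * cin + c) * (onpos * B);
      const double* src0 = xp + (R_xlen_t)c * (npos * B);
      for (int b = 0; b < B; ++b) {
        const double* srcb = src0 + (R_xlen_t)b * npos;
        double* dstb = dst0 + (R_xlen_t)b * onpos;
        for (int z = 0; z < o3; ++z)
          for (int y = 0; y < o2; ++y) {
            const double* s = srcb + ox + (R_xlen_t)(y + oy) * d1 +
                              (R_xlen_t)(z + oz) * d1 * d2;
            double* t = dstb + (R_xlen_t)y * o1 + (R_xlen_t)z * o1 * o2;
            std::copy(s, s + o1, t);
          }
      }
    }
  }
  return col;
}

// im2col of the zero-padded (pad = 2 per side) output gradient, used
// for the transposed convolution that backpropagates to the layer
// input.  dy: (prod(od)*B) x cout over the conv output grid od;
// returns (prod(od+2)*B) x (27*cout).
// [[Rcpp::export]]
NumericMatrix cpp_im2col3_padded(const NumericMatrix& dy, IntegerVector od,
                                 int B) {
  const int o1 = od[0], o2 = od[1], o3 = od[2];
  const int i1 = o1 + 2, i2 = o2 + 2, i3 = o3 + 2;  // original input grid
  const int cout = dy.ncol();
  const R_xlen_t onpos = (R_xlen_t)o1 * o2 * o3;
  const R_xlen_t inpos = (R_xlen_t)i1 * i2 * i3;
  NumericMatrix col(inpos * B, 27 * cout);
  for (int j = 0; j < 27; ++j) {
    const int ox = j % 3, oy = (j / 3) % 3, oz = j / 9;
    for (int k = 0; k < cout; ++k) {
      double* dst0 = col.begin() + (R_xlen_t)(j * cout + k) * (inpos * B);
      const double* src0 = dy.begin() + (R_xlen_t)k * (onpos * B);
      for (int b = 0; b < B; ++b) {
        double* dstb = dst0 + (R_xlen_t)b * inpos;
        const double* srcb = src0 + (R_xlen_t)b * onpos;
        for (int z = 0; z < i3; ++z) {
          const int sz = z + oz - 2;
          for (int y = 0; y < i2; ++y) {
            const int sy = y + oy - 2;
            double* t = dstb + (R_xlen_t)y * i1 + (R_xlen_t)z * i1 * i2;
            std::fill(t, t + i1, 0.0);
            if (sz < 0 || sz >= o3 || sy < 0 || sy >= o2) continue;
            const int x0 = std::max(0, 2 - ox);
            const int x1 = std::min(i1, o1 + 2 - ox);
            if (x1 <= x0) continue;
            const double* s = srcb + (x0 + ox - 2) + (R_xlen_t)sy * o1 +
                              (R_xlen_t)sz * o1 * o2;
            std::copy(s, s + (x1 - x0), t + x0);
          }
        }
      }
    }
  }
  return col;
}
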