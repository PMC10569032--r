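#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Feature maps are stored as column-major arrays of dim (H, W, C).
// im2col lays each k x k x C receptive field out as one row of the
// returned matrix; rows run column-major over the (outH, outW) output
// positions, columns are ordered (dh fastest, then dw, then channel),
// matching the (k*k*C) x Cout weight-matrix layout used by the R side.
// The inner loop over output rows is a contiguous (stride 1) or strided
// copy with the border handling hoisted out.

// [[Rcpp::export(name = ".im2col")]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  NumericMatrix out(outH * outW, k * k * C);
  const double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = (c * k + dw) * k + dh;
        double* pcol = &out(0, col);
        // valid output-row range for this kernel offset
        int oh_lo = 0, oh_hi = outH - 1;
        while (oh_lo <= oh_hi && oh_lo * stride - pad + dh < 0) ++oh_lo;
        while (oh_hi >= oh_lo && oh_hi * stride - pad + dh >= H) --oh_hi;
        for (int ow = 0; ow < outW; ++ow) {
          const int w0 = ow * stride - pad + dw;
          double* po = pcol + (size_t)ow * outH;
          if (w0 < 0 || w0 >= W) {
            std::memset(po, 0, sizeof(double) * outH);
            continue;
          }
          const double* ps = px + ((size_t)c * W + w0) * H;
          if (oh_lo > 0) std::memset(po, 0, sizeof(double) * oh_lo);
          if (oh_hi < outH - 1)
            std::memset(po + oh_hi + 1, 0,
                        sizeof(double) * (outH - 1 - oh_hi));
          if (stride == 1) {
            if (oh_hi >= oh_lo)
              std::memcpy(po + oh_lo, ps + (oh_lo - pad + dh),
                          sizeof(double) * (oh_hi - oh_lo + 1));
          } else {
            for (int oh = oh_lo; oh <= oh_hi; ++oh)
              po[oh] = ps[oh * stride - pad + dh];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col: scatter-adds patch columns back onto the (H, W, C)
// grid. Used for the data gradient of a convolution and for the forward
// pass of the transposed convolution.

// [[Rcpp::export(name = ".col2im")]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int k, int stride, int pad) {
  const int outH = (H + 2 * pad - k) / stride + 1;
  const int outW = (W + 2 * pad - k) / stride + 1;
  NumericVector x(H * W * C);
  double* px = x.begin();
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        const int col = (c * k + dw) * k + dh;
        const double* pcol = &cols(0, col);
        int oh_lo = 0, oh_hi = outH - 1;
        while (oh_lo <= oh_hi && oh_lo * stride - pad + dh < 0) ++oh_lo;
        while (oh_hi >= oh_lo && oh_hi * stride - pad + dh >= H) --oh_hi;
        for (int ow = 0; ow < outW; ++ow) {
          const int w0 = ow * stride - pad + dw;
          if (w0 < 0 || w0 >= W) continue;
          const double* po = pcol + (size_t)ow * outH;
          double* pd = px + ((size_t)c * W + w0) * H - pad + dh;
          if (stride == 1) {
            for (int oh = oh_lo; oh <= oh_hi; ++oh) pd[oh] += po[oh];
          } else {
            for (int oh = oh_lo; oh <= oh_hi; ++oh)
              pd[oh * stride] += po[oh];
          }
        }
      }
    }
  }
  return x;
}
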