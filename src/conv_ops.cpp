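#include <Rcpp.h>
using namespace Rcpp;

// Patch extraction / scatter for 2-D convolution on H x W x C x N arrays
// (column-major, as produced by base::array). Row order of the patch matrix
// is oh fastest, then ow, then n; column order is kr fastest, then kc,
// then c. Out-of-range taps correspond to zero padding.

static inline int out_extent(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int OH = out_extent(H, k, stride, pad);
  const int OW = out_extent(W, k, stride, pad);
  NumericMatrix col(OH * OW * N, k * k * C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *xc = REAL(x) + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int kc = 0; kc < k; ++kc) {
        for (int kr = 0; kr < k; ++kr) {
          const int j = kr + k * (kc + k * c);
          double *cj = &col(0, j);
          for (int ow = 0; ow < OW; ++ow) {
            const int wi = ow * stride + kc - pad;
            if (wi < 0 || wi >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              const int hi = oh * stride + kr - pad;
              if (hi < 0 || hi >= H) continue;
              cj[oh + OH * (ow + OW * n)] = xc[hi + H * wi];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix dcol, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int OH = out_extent(H, k, stride, pad);
  const int OW = out_extent(W, k, stride, pad);
  NumericVector dx((R_xlen_t)H * W * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *xc = REAL(dx) + (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
      for (int kc = 0; kc < k; ++kc) {
        for (int kr = 0; kr < k; ++kr) {
          const int j = kr + k * (kc + k * c);
          const double *cj = &dcol(0, j);
          for (int ow = 0; ow < OW; ++ow) {
            const int wi = ow * stride + kc - pad;
            if (wi < 0 || wi >= W) continue;
            for (int oh = 0; oh < OH; ++oh) {
              const int hi = oh * stride + kr - pad;
              if (hi < 0 || hi >= H) continue;
              xc[hi + H * wi] += cj[oh + OH * (ow + OW * n)];
            }
          }
        }
      }
    }
  }
  return dx;
}
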