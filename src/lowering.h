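// Shared lowering helpers for stride-1 'same' convolution via GEMM.
// colT layout: (H*W*N) rows x (k*k*C) columns, column index kh + k*kw +
// k*k*c matching the column-major flattening of an R kernel array
// [k,k,C,K], so the reshaped kernel matrix multiplies directly. Filling a
// colT column is a sequence of shifted contiguous copies (cache friendly),
// unlike the classic row-major im2col.
#ifndef CONEFINDER_LOWERING_H
#define CONEFINDER_LOWERING_H

#include <RcppArmadillo.h>

inline void im2colT(const double* x, int H, int W, int C, int N,
                    int k, int pad, arma::mat& colT) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        double* dst = colT.colptr(kh + k * kw + k * k * c);
        int dh = kh - pad, dw = kw - pad;
        int lo = std::max(0, -dh), hi = std::min(H, H - dh);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + ((size_t)n * C + c) * HW;
          double* dn = dst + (size_t)n * HW;
          for (int ow = 0; ow < W; ++ow) {
            double* dp = dn + (size_t)ow * H;
            int iw = ow + dw;
            if (iw < 0 || iw >= W) { std::fill(dp, dp + H, 0.0); continue; }
            const double* src = xc + (size_t)iw * H;
            if (lo > 0) std::fill(dp, dp + lo, 0.0);
            if (hi > lo) std::copy(src + lo + dh, src + hi + dh, dp + lo);
            if (hi < H) std::fill(dp + hi, dp + H, 0.0);
          }
        }
      }
}

// transposed col2im: accumulate dcolT (H*W*N x k*k*C) back into dx
inline void col2imT(const arma::mat& dcolT, int H, int W, int C, int N,
                    int k, int pad, double* dx) {
  const size_t HW = (size_t)H * W;
  for (int c = 0; c < C; ++c)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const double* src = dcolT.colptr(kh + k * kw + k * k * c);
        int dh = kh - pad, dw = kw - pad;
        int lo = std::max(0, -dh), hi = std::min(H, H - dh);
        for (int n = 0; n < N; ++n) {
          double* dxc = dx + ((size_t)n * C + c) * HW;
          const double* sn = src + (size_t)n * HW;
          for (int ow = 0; ow < W; ++ow) {
            int iw = ow + dw;
            if (iw < 0 || iw >= W) continue;
            double* dcol_ = dxc + (size_t)iw * H + dh;
            const double* sp = sn + (size_t)ow * H;
            for (int oh = lo; oh < hi; ++oh) dcol_[oh] += sp[oh];
          }
        }
      }
}

// ymT (H*W*N x K) + bias -> y [H,W,K,N], optional fused ReLU
inline void scatter_biasT(const arma::mat& ymT, const double* b, int HW,
                          int K, int N, bool relu, double* out) {
  for (int n = 0; n < N; ++n)
    for (int kk = 0; kk < K; ++kk) {
      const double* src = ymT.colptr(kk) + (size_t)n * HW;
      double* dst = out + (size_t)n * HW * K + (size_t)kk * HW;
      double bb = b[kk];
      for (int i = 0; i < HW; ++i) {
        double v = src[i] + bb;
        dst[i] = (relu && v < 0) ? 0.0 : v;
      }
    }
}

#endif
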