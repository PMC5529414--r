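// Whole-image sliding-window inference. The per-pixel probability map is the
// dominant cost of detection, so this path runs the full forward pass in one
// C++ call with preallocated buffers. Batch-norm layers are folded into the
// preceding convolution / FC weights beforehand (inference-time affine
// identity, done in R), and each ReLU is fused into the preceding write.
#include <RcppArmadillo.h>
#include "lowering.h"
using namespace Rcpp;

// 3x3 stride-2 pool (trailing pad when (H-3) odd), optional fused ReLU
static void pool3s2(const double* x, int H, int W, int C, int N, bool is_max,
                    bool relu, double* y) {
  int Ho = (H - 3 + (H - 3) % 2) / 2 + 1;
  int Wo = (W - 3 + (W - 3) % 2) / 2 + 1;
  const size_t HW = (size_t)H * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = x + ((size_t)n * C + c) * HW;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          double v;
          if (is_max) {
            v = -HUGE_VAL;
            for (int dw = 0; dw < 3; ++dw) {
              int iw = 2 * ow + dw; if (iw >= W) break;
              for (int dh = 0; dh < 3; ++dh) {
                int ih = 2 * oh + dh; if (ih >= H) break;
                double u = xs[(size_t)iw * H + ih];
                if (u > v) v = u;
              }
            }
          } else {
            v = 0.0;
            for (int dw = 0; dw < 3; ++dw) {
              int iw = 2 * ow + dw; if (iw >= W) break;
              for (int dh = 0; dh < 3; ++dh) {
                int ih = 2 * oh + dh; if (ih >= H) break;
                v += xs[(size_t)iw * H + ih];
              }
            }
            v /= 9.0;
          }
          y[o] = (relu && v < 0) ? 0.0 : v;
        }
    }
}

// padded: mirror-padded image (H+32) x (W+32); fp: folded parameters
// w1 25x32, w2 800x32, w3 800x64 (im2col layout), fw1 64x1024, fw2 2x64.
// Returns the H x W map of cone probabilities (class index 1).
// [[Rcpp::export]]
NumericMatrix infer_probmap(NumericMatrix padded, List fp, int chunk) {
  const int Hp = padded.nrow(), Wp = padded.ncol();
  const int H = Hp - 32, W = Wp - 32;
  if (H < 1 || W < 1) stop("padded image too small");
  arma::mat w1 = fp["w1"], w2 = fp["w2"], w3 = fp["w3"];
  arma::mat fw1 = fp["fw1"], fw2 = fp["fw2"];
  arma::vec b1 = fp["b1"], b2 = fp["b2"], b3 = fp["b3"];
  arma::vec fb1 = fp["fb1"], fb2 = fp["fb2"];
  const int total = H * W;
  chunk = std::min(chunk, total);
  // buffers for a full chunk
  std::vector<double> x0((size_t)1089 * chunk);
  std::vector<double> t1((size_t)1089 * 32 * chunk);
  std::vector<double> p1((size_t)256 * 32 * chunk);
  std::vector<double> t2((size_t)256 * 32 * chunk);
  std::vector<double> p2((size_t)64 * 32 * chunk);
  std::vector<double> t3((size_t)64 * 64 * chunk);
  std::vector<double> p3((size_t)16 * 64 * chunk);
  arma::mat col1((size_t)1089 * chunk, 25);
  arma::mat col2((size_t)256 * chunk, 800);
  arma::mat col3((size_t)64 * chunk, 800);
  NumericMatrix map(H, W);
  const double* pp = REAL(padded);
  for (int s = 0; s < total; s += chunk) {
    int nb = std::min(chunk, total - s);
    // gather 33x33 patches; pixel (x, y) -> padded top-left (y, x)
    for (int b = 0; b < nb; ++b) {
      int y0 = (s + b) % H, xcol = (s + b) / H;
      double* dst = x0.data() + (size_t)b * 1089;
      for (int j = 0; j < 33; ++j) {
        const double* src = pp + (size_t)(xcol + j) * Hp + y0;
        std::copy(src, src + 33, dst + (size_t)j * 33);
      }
    }
    im2colT(x0.data(), 33, 33, 1, nb, 5, 2, col1);
    {
      arma::mat ymT = col1.rows(0, (size_t)1089 * nb - 1) * w1;
      scatter_biasT(ymT, b1.memptr(), 1089, 32, nb, false, t1.data());
    }
    pool3s2(t1.data(), 33, 33, 32, nb, true, true, p1.data());   // max + relu
    im2colT(p1.data(), 16, 16, 32, nb, 5, 2, col2);
    {
      arma::mat ymT = col2.rows(0, (size_t)256 * nb - 1) * w2;
      scatter_biasT(ymT, b2.memptr(), 256, 32, nb, true, t2.data());
    }
    pool3s2(t2.data(), 16, 16, 32, nb, false, false, p2.data()); // avg
    im2colT(p2.data(), 8, 8, 32, nb, 5, 2, col3);
    {
      arma::mat ymT = col3.rows(0, (size_t)64 * nb - 1) * w3;
      scatter_biasT(ymT, b3.memptr(), 64, 64, nb, true, t3.data());
    }
    pool3s2(t3.data(), 8, 8, 64, nb, false, false, p3.data());   // avg
    arma::mat f(p3.data(), 1024, nb, false, true);
    arma::mat z1 = fw1 * f;
    z1.each_col() += fb1;
    z1.transform([](double v) { return v < 0 ? 0.0 : v; });
    arma::mat z2 = fw2 * z1;
    z2.each_col() += fb2;
    for (int b = 0; b < nb; ++b) {
      double m = std::max(z2(0, b), z2(1, b));
      double e0 = std::exp(z2(0, b) - m), e1 = std::exp(z2(1, b) - m);
      map[s + b] = e1 / (e0 + e1);
    }
  }
  return map;
}
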