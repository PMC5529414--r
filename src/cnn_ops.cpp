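// Layer kernels for the 33x33-patch cone classifier.
// Layout convention (R column-major): feature maps are 4-D arrays [H, W, C, N],
// conv kernels [k, k, C, K]; im2col row index kh + k*kw + k*k*c matches the
// column-major flattening of the kernel array, so the weight matrix is just a
// reshape.
#include <RcppArmadillo.h>
#include "lowering.h"
using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], K = wd[3];
  if (wd[1] != k || wd[2] != C) stop("kernel dims do not match input channels");
  const int HW = H * W;
  // chunk samples so the lowering buffer stays modest
  int chunk = std::max(1, (int)(4194304 / ((size_t)HW * k * k * C)));
  chunk = std::min(chunk, N);
  arma::mat colT((size_t)HW * chunk, k * k * C);
  arma::mat wm(const_cast<double*>(REAL(w)), k * k * C, K, false, true);
  NumericVector y = alloc4(H, W, K, N);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    int nc = std::min(chunk, N - n0);
    im2colT(REAL(x) + (size_t)n0 * HW * C, H, W, C, nc, k, pad, colT);
    arma::mat ymT = colT.rows(0, (size_t)HW * nc - 1) * wm;
    scatter_biasT(ymT, bp, HW, K, nc, false,
                  yp + (size_t)n0 * HW * K);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int pad, bool want_dx) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = w.attr("dim");
  int k = wd[0], K = wd[3];
  const int HW = H * W;
  int chunk = std::max(1, (int)(4194304 / ((size_t)HW * k * k * C)));
  chunk = std::min(chunk, N);
  arma::mat colT((size_t)HW * chunk, k * k * C);
  arma::mat dymT((size_t)HW * chunk, K);
  arma::mat wm(const_cast<double*>(REAL(w)), k * k * C, K, false, true);
  arma::mat dwm(k * k * C, K, arma::fill::zeros);
  NumericVector db(K);
  NumericVector dx;
  if (want_dx) dx = alloc4(H, W, C, N);
  const double* dyp = REAL(dy);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    int nc = std::min(chunk, N - n0);
    // dy [H,W,K,N] slice -> (HW*nc) x K
    for (int n = 0; n < nc; ++n)
      for (int kk = 0; kk < K; ++kk) {
        const double* src = dyp + (size_t)(n0 + n) * HW * K + (size_t)kk * HW;
        double* dst = dymT.colptr(kk) + (size_t)n * HW;
        std::copy(src, src + HW, dst);
      }
    arma::mat dymv = dymT.rows(0, (size_t)HW * nc - 1);
    im2colT(REAL(x) + (size_t)n0 * HW * C, H, W, C, nc, k, pad, colT);
    dwm += colT.rows(0, (size_t)HW * nc - 1).t() * dymv;
    for (int kk = 0; kk < K; ++kk) db[kk] += arma::accu(dymv.col(kk));
    if (want_dx) {
      arma::mat dcolT = dymv * wm.t();         // (HW*nc) x (k*k*C)
      col2imT(dcolT, H, W, C, nc, k, pad,
              REAL(dx) + (size_t)n0 * HW * C);
    }
  }
  NumericVector dw = alloc4(k, k, C, K);
  std::copy(dwm.begin(), dwm.end(), REAL(dw));
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// 3x3 stride-2 pooling; a single trailing pad row/col is added when needed so
// every input pixel is covered ((H-3) odd). Max pooling ignores the padding,
// average pooling treats it as zeros and always divides by 9.
// [[Rcpp::export]]
List pool3s2_fwd(NumericVector x, std::string type) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  int Ho = (H - 3 + (H - 3) % 2) / 2 + 1;
  int Wo = (W - 3 + (W - 3) % 2) / 2 + 1;
  bool is_max = (type == "max");
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx;
  int* ip = nullptr;
  if (is_max) { idx = IntegerVector((size_t)Ho * Wo * C * N); ip = INTEGER(idx); }
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const size_t HW = (size_t)H * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          int h0 = 2 * oh, w0 = 2 * ow;
          if (is_max) {
            double best = -HUGE_VAL; int bi = -1;
            for (int dw2 = 0; dw2 < 3; ++dw2) {
              int iw = w0 + dw2; if (iw >= W) break;
              for (int dh = 0; dh < 3; ++dh) {
                int ih = h0 + dh; if (ih >= H) break;
                double v = xs[(size_t)iw * H + ih];
                if (v > best) { best = v; bi = iw * H + ih; }
              }
            }
            yp[o] = best;
            ip[o] = bi + (int)(((size_t)n * C + c) * HW);
          } else {
            double s = 0.0;
            for (int dw2 = 0; dw2 < 3; ++dw2) {
              int iw = w0 + dw2; if (iw >= W) break;
              for (int dh = 0; dh < 3; ++dh) {
                int ih = h0 + dh; if (ih >= H) break;
                s += xs[(size_t)iw * H + ih];
              }
            }
            yp[o] = s / 9.0;
          }
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool3s2_bwd(NumericVector dy, IntegerVector xdim,
                          std::string type, IntegerVector idx) {
  int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  NumericVector dx = alloc4(H, W, C, N);
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  if (type == "max") {
    const int* ip = INTEGER(idx);
    R_xlen_t n = dy.size();
    for (R_xlen_t i = 0; i < n; ++i) dxp[ip[i]] += dyp[i];
    return dx;
  }
  int Ho = (H - 3 + (H - 3) % 2) / 2 + 1;
  int Wo = (W - 3 + (W - 3) % 2) / 2 + 1;
  const size_t HW = (size_t)H * W;
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxs = dxp + ((size_t)n * C + c) * HW;
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh, ++o) {
          double g = dyp[o] / 9.0;
          for (int dw2 = 0; dw2 < 3; ++dw2) {
            int iw = 2 * ow + dw2; if (iw >= W) break;
            for (int dh = 0; dh < 3; ++dh) {
              int ih = 2 * oh + dh; if (ih >= H) break;
              dxs[(size_t)iw * H + ih] += g;
            }
          }
        }
    }
  return dx;
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y = clone(x);
  double* yp = REAL(y);
  R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i) if (yp[i] < 0) yp[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector x, NumericVector dy) {
  NumericVector dx = clone(dy);
  const double* xp = REAL(x);
  double* dp = REAL(dx);
  R_xlen_t n = dx.size();
  for (R_xlen_t i = 0; i < n; ++i) if (xp[i] <= 0) dp[i] = 0;
  return dx;
}

// Batch normalisation over all dims except the channel (3rd) dim.
// Variance is the biased (population) estimate over the mini-batch.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector mean(C), var(C);
  const double* xp = REAL(x);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) s += xs[i];
    }
    double mu = s / M, ss = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { double d = xs[i] - mu; ss += d * d; }
    }
    mean[c] = mu; var[c] = ss / M;
  }
  NumericVector y = alloc4(H, W, C, N);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(var[c] + eps), mu = mean[c], be = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      double* ys = yp + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) ys[i] = (xs[i] - mu) * inv + be;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var);
}

// [[Rcpp::export]]
NumericVector bn_infer(NumericVector x, NumericVector gamma, NumericVector beta,
                       NumericVector rmean, NumericVector rvar, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int c = 0; c < C; ++c) {
    double inv = gamma[c] / std::sqrt(rvar[c] + eps), mu = rmean[c], be = beta[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      double* ys = yp + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) ys[i] = (xs[i] - mu) * inv + be;
    }
  }
  return y;
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector gamma, NumericVector mean,
            NumericVector var, NumericVector dy, double eps) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dgamma(C), dbeta(C);
  const double* xp = REAL(x);
  const double* dyp = REAL(dy);
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double mu = mean[c], istd = 1.0 / std::sqrt(var[c] + eps);
    double sdy = 0.0, sdyx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      const double* ds = dyp + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        sdy += ds[i];
        sdyx += ds[i] * (xs[i] - mu) * istd;
      }
    }
    dgamma[c] = sdyx; dbeta[c] = sdy;
    double g = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* xs = xp + ((size_t)n * C + c) * HW;
      const double* ds = dyp + ((size_t)n * C + c) * HW;
      double* dd = dxp + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        double xhat = (xs[i] - mu) * istd;
        dd[i] = g * istd / M * (M * ds[i] - sdy - xhat * sdyx);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Gather 33x33 patches (as [33,33,1,nb]) from a pre-padded image around
// 0-based (row, col) centres given in padded coordinates.
// [[Rcpp::export]]
NumericVector gather_patches(NumericMatrix padded, IntegerVector rows,
                             IntegerVector cols, int half) {
  int k = 2 * half + 1, nb = rows.size(), H = padded.nrow();
  NumericVector out = alloc4(k, k, 1, nb);
  double* op = REAL(out);
  const double* pp = REAL(padded);
  for (int b = 0; b < nb; ++b) {
    int r0 = rows[b] - half, c0 = cols[b] - half;
    double* dst = op + (size_t)b * k * k;
    for (int j = 0; j < k; ++j) {
      const double* src = pp + (size_t)(c0 + j) * H + r0;
      std::copy(src, src + k, dst + (size_t)j * k);
    }
  }
  return out;
}
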