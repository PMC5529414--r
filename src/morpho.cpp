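// Grayscale morphological reconstruction (hybrid raster/queue algorithm),
// regional maxima, 8-connected component labelling, and a separable Gaussian
// filter. All neighbourhoods are 8-connected, matching MATLAB's 2-D defaults.
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Reconstruction by dilation of marker under mask (marker <= mask required).
// [[Rcpp::export]]
NumericMatrix grey_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  int H = marker.nrow(), W = marker.ncol();
  if (mask.nrow() != H || mask.ncol() != W) stop("marker/mask size mismatch");
  NumericMatrix J = clone(marker);
  for (int i = 0; i < H * W; ++i)
    if (J[i] > mask[i]) stop("marker must be <= mask everywhere");
  // raster scan: propagate from already-visited neighbours
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double m = J(r, c);
      if (r > 0)            m = std::max(m, J(r - 1, c));
      if (c > 0)            m = std::max(m, J(r, c - 1));
      if (r > 0 && c > 0)   m = std::max(m, J(r - 1, c - 1));
      if (r < H - 1 && c > 0) m = std::max(m, J(r + 1, c - 1));
      J(r, c) = std::min(m, mask(r, c));
    }
  // anti-raster scan + seed queue
  std::queue<int> q;
  for (int c = W - 1; c >= 0; --c)
    for (int r = H - 1; r >= 0; --r) {
      double m = J(r, c);
      if (r < H - 1)              m = std::max(m, J(r + 1, c));
      if (c < W - 1)              m = std::max(m, J(r, c + 1));
      if (r < H - 1 && c < W - 1) m = std::max(m, J(r + 1, c + 1));
      if (r > 0 && c < W - 1)     m = std::max(m, J(r - 1, c + 1));
      J(r, c) = std::min(m, mask(r, c));
      // queue if a later-scanned neighbour could still grow
      bool push = false;
      const int dr[4] = { 1, 0, 1, -1 }, dc[4] = { 0, 1, 1, 1 };
      for (int k = 0; k < 4 && !push; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) push = true;
      }
      if (push) q.push(c * H + r);
    }
  const int dr8[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dc8[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int r = p % H, c = p / H;
    double v = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (J(rr, cc) < v && J(rr, cc) < mask(rr, cc)) {
        J(rr, cc) = std::min(v, mask(rr, cc));
        q.push(cc * H + rr);
      }
    }
  }
  return J;
}

// Regional maxima: 8-connected plateaus strictly greater than all neighbours.
// [[Rcpp::export]]
LogicalMatrix regional_maxima(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  LogicalMatrix out(H, W);
  std::vector<char> visited((size_t)H * W, 0);
  const int dr8[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dc8[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  std::vector<int> plateau;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      int p0 = c0 * H + r0;
      if (visited[p0]) continue;
      double v = img(r0, c0);
      bool is_max = true;
      plateau.clear();
      std::queue<int> q;
      q.push(p0); visited[p0] = 1;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        plateau.push_back(p);
        int r = p % H, c = p / H;
        for (int k = 0; k < 8; ++k) {
          int rr = r + dr8[k], cc = c + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          double u = img(rr, cc);
          if (u > v) is_max = false;
          else if (u == v && !visited[cc * H + rr]) {
            visited[cc * H + rr] = 1;
            q.push(cc * H + rr);
          }
        }
      }
      if (is_max)
        for (int p : plateau) out[p] = true;
    }
  return out;
}

// 8-connected component labelling of a binary mask; 0 = background.
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dc8[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  int next = 0;
  for (int c0 = 0; c0 < W; ++c0)
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      std::queue<int> q;
      q.push(c0 * H + r0);
      lab(r0, c0) = next;
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int r = p % H, c = p / H;
        for (int k = 0; k < 8; ++k) {
          int rr = r + dr8[k], cc = c + dc8[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(cc * H + rr);
          }
        }
      }
    }
  return lab;
}

// Separable Gaussian filter, kernel truncated at 4*sigma, half-sample
// symmetric (edge-duplicating) boundary. sigma = 0 returns a copy.
// [[Rcpp::export]]
NumericMatrix gaussian_blur(NumericMatrix img, double sigma) {
  if (sigma < 0) stop("sigma must be >= 0");
  if (sigma == 0) return clone(img);
  int H = img.nrow(), W = img.ncol();
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (double& v : ker) v /= s;
  auto reflect = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - 1 - i; }
    return i;
  };
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += ker[i + rad] * img(reflect(r + i, H), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += ker[i + rad] * tmp(r, reflect(c + i, W));
      out(r, c) = acc;
    }
  return out;
}
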