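#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect (symmetric, edge included) index into [0, n): -1 -> 0, n -> n-1.
static inline int refl(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Separable convolution with a normalised 1-D kernel, reflect padding.
// [[Rcpp::export(name = ".gaussian_sep_cpp")]]
NumericMatrix gaussian_sep_cpp(NumericMatrix m, NumericVector kern) {
  int H = m.nrow(), W = m.ncol(), K = kern.size(), r = K / 2;
  NumericMatrix tmp(H, W), out(H, W);
  for (int i = 0; i < H; ++i)      // horizontal pass
    for (int j = 0; j < W; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += kern[k] * m(i, refl(j + k - r, W));
      tmp(i, j) = s;
    }
  for (int j = 0; j < W; ++j)      // vertical pass
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += kern[k] * tmp(refl(i + k - r, H), j);
      out(i, j) = s;
    }
  return out;
}

// [[Rcpp::export(name = ".median_cpp")]]
NumericMatrix median_cpp(NumericMatrix m, int ksize) {
  int H = m.nrow(), W = m.ncol(), r = ksize / 2, n = ksize * ksize;
  NumericMatrix out(H, W);
  std::vector<double> buf(n);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int t = 0;
      for (int di = -r; di <= r; ++di)
        for (int dj = -r; dj <= r; ++dj)
          buf[t++] = m(refl(i + di, H), refl(j + dj, W));
      // median of n values (n odd for odd ksize)
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(i, j) = buf[n / 2];
    }
  return out;
}

// Grayscale dilation (max) or erosion (min) by an arbitrary flat structuring
// element, reflect padding.
// [[Rcpp::export(name = ".morph_cpp")]]
NumericMatrix morph_cpp(NumericMatrix m, LogicalMatrix se, bool dilate) {
  int H = m.nrow(), W = m.ncol(), K = se.nrow(), r = K / 2;
  std::vector<int> odi, odj;
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b)
      if (se(a, b)) { odi.push_back(a - r); odj.push_back(b - r); }
  NumericMatrix out(H, W);
  size_t n = odi.size();
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double v = m(refl(i + odi[0], H), refl(j + odj[0], W));
      for (size_t k = 1; k < n; ++k) {
        double u = m(refl(i + odi[k], H), refl(j + odj[k], W));
        if (dilate ? (u > v) : (u < v)) v = u;
      }
      out(i, j) = v;
    }
  return out;
}

// 8-connected component labelling of a logical mask; labels 1..n in scan
// order of each component's first pixel, 0 for background.
// [[Rcpp::export(name = ".label_cpp")]]
IntegerMatrix label_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}
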