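// Fast-marching inpainting: propagate the mask boundary inward in order of
// distance T (|grad T| = 1, T = 0 on the initial boundary), estimating each
// unknown pixel from its known neighbours by the normalised first-order
// weighted sum.
#include <Rcpp.h>
#include <set>
#include <cmath>
#include <vector>
#include <tuple>
using namespace Rcpp;

static const int F_KNOWN = 0, F_BAND = 1, F_INSIDE = 2;
static const double T_INF = 1e6;

static inline int refl2(int i, int n) {
  if (i < 0) return -1 - i;
  if (i >= n) return 2 * n - 1 - i;
  return i;
}

// Quadratic upwind solve of the discrete eikonal |grad T| = 1 at (i, j),
// using the smallest finalised horizontal and vertical neighbour values.
static double eikonal_solve(const NumericMatrix& T, const IntegerMatrix& fl,
                            int i, int j) {
  int H = T.nrow(), W = T.ncol();
  double th = T_INF, tv = T_INF;
  if (i > 0 && fl(i - 1, j) == F_KNOWN) tv = std::min(tv, T(i - 1, j));
  if (i < H - 1 && fl(i + 1, j) == F_KNOWN) tv = std::min(tv, T(i + 1, j));
  if (j > 0 && fl(i, j - 1) == F_KNOWN) th = std::min(th, T(i, j - 1));
  if (j < W - 1 && fl(i, j + 1) == F_KNOWN) th = std::min(th, T(i, j + 1));
  double a = std::min(th, tv), b = std::max(th, tv);
  if (a >= T_INF) return T_INF;
  if (b >= T_INF || b - a >= 1.0) return a + 1.0; // 1-D degenerate solve
  double disc = 2.0 - (th - tv) * (th - tv);
  return (th + tv + std::sqrt(disc)) / 2.0;
}

typedef std::set<std::tuple<double, int, int> > Band;

// March from the given band pixels into pixels flagged F_INSIDE, filling T.
// Returns the sequence of popped T values (non-decreasing by construction).
static std::vector<double> march(NumericMatrix& T, IntegerMatrix& fl,
                                 Band& band) {
  int H = T.nrow(), W = T.ncol();
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  std::vector<double> pops;
  while (!band.empty()) {
    std::tuple<double, int, int> top = *band.begin();
    band.erase(band.begin());
    int i = std::get<1>(top), j = std::get<2>(top);
    fl(i, j) = F_KNOWN;
    pops.push_back(std::get<0>(top));
    for (int k = 0; k < 4; ++k) {
      int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
      int f = fl(ni, nj);
      if (f == F_KNOWN) continue;
      double t = eikonal_solve(T, fl, ni, nj);
      if (f == F_INSIDE) {
        fl(ni, nj) = F_BAND;
        T(ni, nj) = t;
        band.insert(std::make_tuple(t, ni, nj));
      } else if (t < T(ni, nj)) { // F_BAND: decrease key
        band.erase(std::make_tuple(T(ni, nj), ni, nj));
        T(ni, nj) = t;
        band.insert(std::make_tuple(t, ni, nj));
      }
    }
  }
  return pops;
}

// Signed distance-to-boundary field for a mask. Inside the mask T > 0 is the
// fast-marching distance to the initial boundary (the known pixels adjacent
// to the mask, where T = 0); outside it is the negated analogous distance.
// flag: 0 = KNOWN (outside), 1 = BAND (initial boundary), 2 = INSIDE (mask).
// [[Rcpp::export(name = ".fmm_distance_cpp")]]
List fmm_distance_cpp(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  NumericMatrix T(H, W);
  IntegerMatrix flag(H, W);
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};

  int nmask = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (mask(i, j)) ++nmask;
  if (nmask == 0)
    return List::create(_["T"] = T, _["flag"] = flag,
                        _["pops"] = NumericVector(0));

  // initial boundary: known pixels 4-adjacent to the mask
  std::vector<std::pair<int, int> > bnd;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j)) continue;
      for (int k = 0; k < 4; ++k) {
        int ni = i + di[k], nj = j + dj[k];
        if (ni >= 0 && nj >= 0 && ni < H && nj < W && mask(ni, nj)) {
          bnd.push_back(std::make_pair(i, j));
          break;
        }
      }
    }

  // inward pass
  NumericMatrix Tin(H, W);
  IntegerMatrix fin(H, W);
  Band band;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      fin(i, j) = mask(i, j) ? F_INSIDE : F_KNOWN;
      Tin(i, j) = mask(i, j) ? T_INF : 0.0;
    }
  for (size_t b = 0; b < bnd.size(); ++b) {
    fin(bnd[b].first, bnd[b].second) = F_BAND;
    band.insert(std::make_tuple(0.0, bnd[b].first, bnd[b].second));
  }
  std::vector<double> pops = march(Tin, fin, band);

  // outward pass over the known region (for the level-set weight component)
  NumericMatrix Tout(H, W);
  IntegerMatrix fout(H, W);
  Band band2;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      fout(i, j) = mask(i, j) ? F_KNOWN : F_INSIDE;
      Tout(i, j) = mask(i, j) ? 0.0 : T_INF;
    }
  for (size_t b = 0; b < bnd.size(); ++b) {
    int bi = bnd[b].first, bj = bnd[b].second;
    fout(bi, bj) = F_BAND;
    Tout(bi, bj) = 0.0;
    band2.insert(std::make_tuple(0.0, bi, bj));
  }
  march(Tout, fout, band2);

  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j)) {
        T(i, j) = Tin(i, j);
        flag(i, j) = F_INSIDE;
      } else {
        T(i, j) = -Tout(i, j);
        flag(i, j) = F_KNOWN;
      }
    }
  for (size_t b = 0; b < bnd.size(); ++b) {
    T(bnd[b].first, bnd[b].second) = 0.0;
    flag(bnd[b].first, bnd[b].second) = F_BAND;
  }
  return List::create(_["T"] = T, _["flag"] = flag,
                      _["pops"] = NumericVector(pops.begin(), pops.end()));
}

// One first-order estimate at (pi, pj) from known pixels in the Chebyshev
// eps-ball, weighted by direction, geometric distance and level-set distance.
static void telea_estimate(std::vector<NumericMatrix>& ch,
                           const LogicalMatrix& known,
                           const NumericMatrix& T,
                           int pi, int pj, double eps,
                           double d0, double t0) {
  int H = T.nrow(), W = T.ncol(), nch = ch.size();
  int r = (int)std::ceil(eps);
  // boundary normal: gradient of T at p (central differences, reflected)
  double ny = (T(refl2(pi + 1, H), pj) - T(refl2(pi - 1, H), pj)) / 2.0;
  double nx = (T(pi, refl2(pj + 1, W)) - T(pi, refl2(pj - 1, W))) / 2.0;
  double nl = std::sqrt(ny * ny + nx * nx);
  if (nl > 1e-12) { ny /= nl; nx /= nl; } else { ny = 0.0; nx = 0.0; }

  std::vector<double> acc(nch, 0.0);
  double wsum = 0.0;
  for (int qi = pi - r; qi <= pi + r; ++qi)
    for (int qj = pj - r; qj <= pj + r; ++qj) {
      if (qi < 0 || qj < 0 || qi >= H || qj >= W) continue;
      if (qi == pi && qj == pj) continue;
      if (std::max(std::abs(qi - pi), std::abs(qj - pj)) > eps) continue;
      if (!known(qi, qj)) continue;
      double dy = pi - qi, dx = pj - qj;
      double len2 = dy * dy + dx * dx, len = std::sqrt(len2);
      double dir = std::abs(dy * ny + dx * nx) / len;
      if (dir <= 1e-6) dir = 1e-6;
      double dst = (d0 * d0) / len2;
      double lev = t0 / (t0 + std::abs(T(pi, pj) - T(qi, qj)));
      double w = dir * dst * lev;
      // image gradient at q from known neighbours only (central, one-sided
      // at known/unknown interfaces, zero when isolated)
      for (int c = 0; c < nch; ++c) {
        double gy = 0.0, gx = 0.0;
        bool up = qi > 0 && known(qi - 1, qj), dn = qi < H - 1 && known(qi + 1, qj);
        bool lf = qj > 0 && known(qi, qj - 1), rt = qj < W - 1 && known(qi, qj + 1);
        const NumericMatrix& I = ch[c];
        if (up && dn) gy = (I(qi + 1, qj) - I(qi - 1, qj)) / 2.0;
        else if (dn) gy = I(qi + 1, qj) - I(qi, qj);
        else if (up) gy = I(qi, qj) - I(qi - 1, qj);
        if (lf && rt) gx = (I(qi, qj + 1) - I(qi, qj - 1)) / 2.0;
        else if (rt) gx = I(qi, qj + 1) - I(qi, qj);
        else if (lf) gx = I(qi, qj) - I(qi, qj - 1);
        acc[c] += w * (I(qi, qj) + gy * dy + gx * dx);
      }
      wsum += w;
    }
  if (wsum <= 0.0) { // unreachable under marching order; average fallback
    int n = 0;
    for (int c = 0; c < nch; ++c) acc[c] = 0.0;
    for (int qi = pi - 1; qi <= pi + 1; ++qi)
      for (int qj = pj - 1; qj <= pj + 1; ++qj) {
        if (qi < 0 || qj < 0 || qi >= H || qj >= W) continue;
        if (!known(qi, qj)) continue;
        for (int c = 0; c < nch; ++c) acc[c] += ch[c](qi, qj);
        ++n;
      }
    wsum = n > 0 ? n : 1;
  }
  for (int c = 0; c < nch; ++c) {
    double v = acc[c] / wsum;
    ch[c](pi, pj) = v < 0.0 ? 0.0 : (v > 255.0 ? 255.0 : v);
  }
}

// Inpaint the masked region of a multi-channel image. Channels share the
// distance field and weights. Returns the filled channels plus the signed T
// field and the processed-pixel T sequence (for order auditing).
// [[Rcpp::export(name = ".inpaint_cpp")]]
List inpaint_cpp(List channels, LogicalMatrix mask, double eps,
                 double d0, double t0) {
  int nch = channels.size();
  std::vector<NumericMatrix> ch(nch);
  for (int c = 0; c < nch; ++c) ch[c] = clone(as<NumericMatrix>(channels[c]));
  int H = mask.nrow(), W = mask.ncol();

  List df = fmm_distance_cpp(mask);
  NumericMatrix T = df["T"];

  // process mask pixels in non-decreasing (T, row, col) order
  Band order;
  LogicalMatrix known(H, W);
  int nmask = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      known(i, j) = !mask(i, j);
      if (mask(i, j)) {
        order.insert(std::make_tuple(T(i, j), i, j));
        ++nmask;
      }
    }
  NumericVector seq(nmask);
  int t = 0;
  for (Band::iterator it = order.begin(); it != order.end(); ++it) {
    int i = std::get<1>(*it), j = std::get<2>(*it);
    telea_estimate(ch, known, T, i, j, eps, d0, t0);
    known(i, j) = true;
    seq[t++] = std::get<0>(*it);
  }
  List out(nch);
  for (int c = 0; c < nch; ++c) out[c] = ch[c];
  return List::create(_["channels"] = out, _["T"] = T, _["order"] = seq);
}
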