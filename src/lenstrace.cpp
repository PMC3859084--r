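#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Pixel convention shared with the R side: x = column, y = row, both
// 0-based, pixel centers at integer coordinates. An image is an R matrix
// indexed [y + 1, x + 1].

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Canny edge detection: separable Gaussian blur, Sobel gradients,
// non-maximum suppression along the quantized gradient direction, double
// threshold with hysteresis (8-connected BFS from strong pixels).
// high <= 0 requests an Otsu threshold on the gradient-magnitude histogram,
// with low = high / 2.
// ---------------------------------------------------------------------------

static std::vector<double> gauss_kernel(double sigma) {
  int r = (int)std::ceil(3.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
IntegerMatrix cpp_canny(NumericMatrix img, double sigma, double low,
                        double high) {
  const int h = img.nrow(), w = img.ncol();
  std::vector<double> a(img.begin(), img.end());  // column-major
  std::vector<double> b(a.size());

  if (sigma > 0) {
    std::vector<double> k = gauss_kernel(sigma);
    const int r = ((int)k.size() - 1) / 2;
    // vertical pass (within columns), reflected borders
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        double s = 0.0;
        for (int i = -r; i <= r; ++i) {
          int yy = y + i;
          if (yy < 0) yy = -yy;
          if (yy >= h) yy = 2 * h - 2 - yy;
          s += k[i + r] * a[(size_t)x * h + yy];
        }
        b[(size_t)x * h + y] = s;
      }
    // horizontal pass
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        double s = 0.0;
        for (int i = -r; i <= r; ++i) {
          int xx = x + i;
          if (xx < 0) xx = -xx;
          if (xx >= w) xx = 2 * w - 2 - xx;
          s += k[i + r] * b[(size_t)xx * h + y];
        }
        a[(size_t)x * h + y] = s;
      }
  }

  std::vector<double> mag(a.size(), 0.0);
  std::vector<unsigned char> dir(a.size(), 0);
  auto at = [&](int y, int x) {
    return a[(size_t)clampi(x, 0, w - 1) * h + clampi(y, 0, h - 1)];
  };
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      double gx = (at(y - 1, x + 1) + 2 * at(y, x + 1) + at(y + 1, x + 1)) -
                  (at(y - 1, x - 1) + 2 * at(y, x - 1) + at(y + 1, x - 1));
      double gy = (at(y + 1, x - 1) + 2 * at(y + 1, x) + at(y + 1, x + 1)) -
                  (at(y - 1, x - 1) + 2 * at(y - 1, x) + at(y - 1, x + 1));
      size_t idx = (size_t)x * h + y;
      mag[idx] = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      unsigned char d;  // 0: E-W, 1: NE-SW, 2: N-S, 3: NW-SE
      if (ang < 22.5 || ang >= 157.5) d = 0;
      else if (ang < 67.5) d = 1;
      else if (ang < 112.5) d = 2;
      else d = 3;
      dir[idx] = d;
    }

  if (high <= 0) {  // Otsu on the positive gradient magnitudes
    double mmax = *std::max_element(mag.begin(), mag.end());
    if (mmax <= 0) return IntegerMatrix(h, w);
    const int nb = 256;
    std::vector<double> hist(nb, 0.0);
    double tot = 0.0;
    for (double m : mag)
      if (m > 0) {
        int bin = (int)(m / mmax * (nb - 1));
        hist[bin] += 1.0;
        tot += 1.0;
      }
    double sum = 0.0;
    for (int i = 0; i < nb; ++i) sum += i * hist[i];
    double sumB = 0.0, wB = 0.0, best = -1.0;
    int thr = nb / 2;
    for (int i = 0; i < nb; ++i) {
      wB += hist[i];
      if (wB == 0) continue;
      double wF = tot - wB;
      if (wF == 0) break;
      sumB += i * hist[i];
      double mB = sumB / wB, mF = (sum - sumB) / wF;
      double between = wB * wF * (mB - mF) * (mB - mF);
      if (between > best) { best = between; thr = i; }
    }
    high = (thr + 0.5) / (nb - 1) * mmax;
    low = high / 2.0;
  }

  // non-maximum suppression
  const int dy4[4] = {0, -1, -1, -1};
  const int dx4[4] = {1, 1, 0, -1};
  std::vector<unsigned char> state(a.size(), 0);  // 1 weak, 2 strong
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      size_t idx = (size_t)x * h + y;
      double m = mag[idx];
      if (m < low) continue;
      int d = dir[idx];
      int y1 = clampi(y + dy4[d], 0, h - 1), x1 = clampi(x + dx4[d], 0, w - 1);
      int y2 = clampi(y - dy4[d], 0, h - 1), x2 = clampi(x - dx4[d], 0, w - 1);
      if (m >= mag[(size_t)x1 * h + y1] && m >= mag[(size_t)x2 * h + y2])
        state[idx] = (m >= high) ? 2 : 1;
    }

  // hysteresis
  IntegerMatrix out(h, w);
  std::vector<size_t> stack;
  for (size_t idx = 0; idx < state.size(); ++idx)
    if (state[idx] == 2) { out[idx] = 1; stack.push_back(idx); }
  while (!stack.empty()) {
    size_t idx = stack.back(); stack.pop_back();
    int x = (int)(idx / h), y = (int)(idx % h);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        int xx = x + dx, yy = y + dy;
        if (xx < 0 || xx >= w || yy < 0 || yy >= h) continue;
        size_t j = (size_t)xx * h + yy;
        if (state[j] == 1 && out[j] == 0) { out[j] = 1; stack.push_back(j); }
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Closed-polyline rasterization (8-connected Bresenham) and distance-field
// scoring: mean of dt over the distinct rasterized boundary pixels.
// Out-of-field coordinates are clamped to the border, so clipped vertices
// contribute the border distance value.
// ---------------------------------------------------------------------------

static void raster_segment(int x0, int y0, int x1, int y1,
                           std::vector<int>& xs, std::vector<int>& ys) {
  int dx = std::abs(x1 - x0), sx = x0 < x1 ? 1 : -1;
  int dy = -std::abs(y1 - y0), sy = y0 < y1 ? 1 : -1;
  int err = dx + dy;
  int x = x0, y = y0;
  while (true) {
    xs.push_back(x); ys.push_back(y);
    if (x == x1 && y == y1) break;
    int e2 = 2 * err;
    if (e2 >= dy) { err += dy; x += sx; }
    if (e2 <= dx) { err += dx; y += sy; }
  }
}

static void raster_closed(const double* px, const double* py, int m,
                          std::vector<int>& xs, std::vector<int>& ys) {
  for (int i = 0; i < m; ++i) {
    int j = (i + 1) % m;
    int x0 = (int)std::lround(px[i]), y0 = (int)std::lround(py[i]);
    int x1 = (int)std::lround(px[j]), y1 = (int)std::lround(py[j]);
    raster_segment(x0, y0, x1, y1, xs, ys);
    xs.pop_back(); ys.pop_back();  // endpoint re-added by the next segment
  }
}

// [[Rcpp::export]]
NumericVector cpp_score_polylines(NumericMatrix X, NumericMatrix Y,
                                  NumericMatrix dt) {
  const int n = X.nrow(), m = X.ncol();
  const int h = dt.nrow(), w = dt.ncol();
  NumericVector out(n);
  std::vector<int> xs, ys;
  std::vector<int> stamp((size_t)h * w, -1);
  for (int i = 0; i < n; ++i) {
    xs.clear(); ys.clear();
    std::vector<double> px(m), py(m);
    for (int j = 0; j < m; ++j) { px[j] = X(i, j); py[j] = Y(i, j); }
    raster_closed(px.data(), py.data(), m, xs, ys);
    double s = 0.0; int cnt = 0;
    for (size_t k = 0; k < xs.size(); ++k) {
      int x = clampi(xs[k], 0, w - 1), y = clampi(ys[k], 0, h - 1);
      size_t idx = (size_t)x * h + y;
      if (stamp[idx] == i) continue;
      stamp[idx] = i;
      s += dt[idx];
      ++cnt;
    }
    out[i] = cnt ? s / cnt : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_raster_polyline(NumericVector x, NumericVector y) {
  std::vector<int> xs, ys;
  std::vector<double> px(x.begin(), x.end()), py(y.begin(), y.end());
  raster_closed(px.data(), py.data(), (int)px.size(), xs, ys);
  // distinct pixels, order of first visit
  IntegerMatrix tmp((int)xs.size(), 2);
  std::vector<std::pair<int,int> > seen;
  int n = 0;
  for (size_t k = 0; k < xs.size(); ++k) {
    std::pair<int,int> p(xs[k], ys[k]);
    if (std::find(seen.begin(), seen.end(), p) != seen.end()) continue;
    seen.push_back(p);
    tmp(n, 0) = p.first; tmp(n, 1) = p.second; ++n;
  }
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i,0) = tmp(i,0); out(i,1) = tmp(i,1); }
  return out;
}

// ---------------------------------------------------------------------------
// Point-in-polygon (even-odd ray casting) for one query point against many
// polygons given as row-wise vertex matrices.
// ---------------------------------------------------------------------------

static bool point_in_poly(const double* px, const double* py, int m,
                          double qx, double qy) {
  bool inside = false;
  for (int i = 0, j = m - 1; i < m; j = i++) {
    if (((py[i] > qy) != (py[j] > qy)) &&
        (qx < (px[j] - px[i]) * (qy - py[i]) / (py[j] - py[i]) + px[i]))
      inside = !inside;
  }
  return inside;
}

// [[Rcpp::export]]
LogicalVector cpp_point_in_polygons(NumericMatrix X, NumericMatrix Y,
                                    double qx, double qy) {
  const int n = X.nrow(), m = X.ncol();
  LogicalVector out(n);
  std::vector<double> px(m), py(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) { px[j] = X(i, j); py[j] = Y(i, j); }
    out[i] = point_in_poly(px.data(), py.data(), m, qx, qy);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Polygon interior mask by even-odd scanline fill over pixel centers.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_fill_polygon(NumericVector x, NumericVector y, int w,
                               int h) {
  const int m = x.size();
  IntegerMatrix out(h, w);
  std::vector<double> xs;
  for (int yy = 0; yy < h; ++yy) {
    double qy = (double)yy;
    xs.clear();
    for (int i = 0, j = m - 1; i < m; j = i++) {
      double yi = y[i], yj = y[j];
      if ((yi > qy) != (yj > qy))
        xs.push_back(x[i] + (qy - yi) / (yj - yi) * (x[j] - x[i]));
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int x0 = (int)std::ceil(xs[k]), x1 = (int)std::floor(xs[k + 1]);
      for (int xx = std::max(0, x0); xx <= std::min(w - 1, x1); ++xx)
        out(yy, xx) = 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Agglomerative clustering of axis-aligned boxes: repeatedly merge the pair
// with the largest mutual overlap fraction
//   overlap(i, j) = area(i ∩ j) / min(area(i), area(j))
// while it is >= alpha. Merging replaces both boxes by their enclosing
// rectangle. Ties break toward the earliest pair in input order. Returns a
// 1-based cluster id per input box.
// ---------------------------------------------------------------------------

static double box_overlap(const double* b, int i, int j, int n) {
  double x0 = std::max(b[i], b[j]), y0 = std::max(b[i + n], b[j + n]);
  double x1 = std::min(b[i + 2 * n], b[j + 2 * n]);
  double y1 = std::min(b[i + 3 * n], b[j + 3 * n]);
  double inter = std::max(0.0, x1 - x0) * std::max(0.0, y1 - y0);
  double ai = (b[i + 2 * n] - b[i]) * (b[i + 3 * n] - b[i + n]);
  double aj = (b[j + 2 * n] - b[j]) * (b[j + 3 * n] - b[j + n]);
  double dmin = std::min(ai, aj);
  return dmin > 0 ? inter / dmin : 0.0;
}

struct BestCand {
  double v;
  int i, stamp;  // cluster index and its version stamp at push
};
struct BestCandLess {
  bool operator()(const BestCand& a, const BestCand& b) const {
    if (a.v != b.v) return a.v < b.v;
    return a.i > b.i;  // ties toward earliest cluster
  }
};

// [[Rcpp::export]]
IntegerVector cpp_cluster_bboxes(NumericMatrix bbox, double alpha) {
  const int n = bbox.nrow();
  std::vector<double> b(bbox.begin(), bbox.end());  // x0 y0 x1 y1 columns
  std::vector<int> root(n), version(n, 0), besti(n, -1);
  std::vector<double> bestv(n, -1.0);
  std::vector<bool> active(n, true), dirty(n, false);
  for (int i = 0; i < n; ++i) root[i] = i;

  auto recompute = [&](int i) {
    bestv[i] = -1.0; besti[i] = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i || !active[j]) continue;
      double v = box_overlap(b.data(), i, j, n);
      if (v > bestv[i]) { bestv[i] = v; besti[i] = j; }
    }
    dirty[i] = false;
  };

  // per-cluster best partner in a lazy max-queue; a cluster whose best
  // partner merged away is marked dirty and recomputed only if it
  // surfaces at the top, keeping total work near O(n^2)
  std::priority_queue<BestCand, std::vector<BestCand>, BestCandLess> pq;
  for (int i = 0; i < n; ++i) {
    recompute(i);
    if (bestv[i] >= alpha) pq.push(BestCand{bestv[i], i, 0});
  }

  while (!pq.empty()) {
    BestCand c = pq.top(); pq.pop();
    int i = c.i;
    if (!active[i] || version[i] != c.stamp) continue;
    if (dirty[i]) {
      recompute(i);
      ++version[i];
      if (bestv[i] >= alpha) pq.push(BestCand{bestv[i], i, version[i]});
      continue;
    }
    int j = besti[i];
    if (!active[j]) {  // partner vanished since push
      dirty[i] = true;
      recompute(i);
      ++version[i];
      if (bestv[i] >= alpha) pq.push(BestCand{bestv[i], i, version[i]});
      continue;
    }
    double vcur = box_overlap(b.data(), i, j, n);
    if (vcur != c.v) {  // partner's box changed since push
      recompute(i);
      ++version[i];
      if (bestv[i] >= alpha) pq.push(BestCand{bestv[i], i, version[i]});
      continue;
    }
    // merge j into a = min(i, j)
    int a = std::min(i, j), d = std::max(i, j);
    b[a] = std::min(b[a], b[d]);
    b[a + n] = std::min(b[a + n], b[d + n]);
    b[a + 2 * n] = std::max(b[a + 2 * n], b[d + 2 * n]);
    b[a + 3 * n] = std::max(b[a + 3 * n], b[d + 3 * n]);
    active[d] = false;
    for (int k = 0; k < n; ++k) if (root[k] == d) root[k] = a;
    recompute(a);
    ++version[a];
    if (bestv[a] >= alpha) pq.push(BestCand{bestv[a], a, version[a]});
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == a) continue;
      double v = box_overlap(b.data(), k, a, n);
      if (besti[k] == a || besti[k] == d) {
        if (v >= bestv[k]) {  // merged cluster is still k's best
          bestv[k] = v; besti[k] = a; dirty[k] = false;
          ++version[k];
          if (v >= alpha) pq.push(BestCand{v, k, version[k]});
        } else {  // stale best: re-queue at the old value as upper bound
          dirty[k] = true;
          ++version[k];
          if (bestv[k] >= alpha) pq.push(BestCand{bestv[k], k, version[k]});
        }
      } else if (v > bestv[k]) {
        bestv[k] = v; besti[k] = a;
        ++version[k];
        if (v >= alpha) pq.push(BestCand{v, k, version[k]});
      }
    }
  }

  IntegerVector out(n);
  std::vector<int> relab(n, 0);
  int nc = 0;
  for (int i = 0; i < n; ++i) {
    int r = root[i];
    if (relab[r] == 0) relab[r] = ++nc;
    out[i] = relab[r];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Rendering helpers for the synthetic scene generator: anti-aliased
// coverage maps for stroked segment sets and filled ellipses. Coverage is
// in [0, 1]; the R side composes it onto the background.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_stroke_coverage(NumericMatrix segs, int w, int h,
                                  double width) {
  NumericMatrix cov(h, w);
  const double r = width / 2.0;
  for (int s = 0; s < segs.nrow(); ++s) {
    double x0 = segs(s, 0), y0 = segs(s, 1), x1 = segs(s, 2), y1 = segs(s, 3);
    int xa = clampi((int)std::floor(std::min(x0, x1) - r - 1), 0, w - 1);
    int xb = clampi((int)std::ceil(std::max(x0, x1) + r + 1), 0, w - 1);
    int ya = clampi((int)std::floor(std::min(y0, y1) - r - 1), 0, h - 1);
    int yb = clampi((int)std::ceil(std::max(y0, y1) + r + 1), 0, h - 1);
    double dx = x1 - x0, dy = y1 - y0;
    double L2 = dx * dx + dy * dy;
    for (int x = xa; x <= xb; ++x)
      for (int y = ya; y <= yb; ++y) {
        double t = L2 > 0 ? ((x - x0) * dx + (y - y0) * dy) / L2 : 0.0;
        t = std::max(0.0, std::min(1.0, t));
        double ddx = x - (x0 + t * dx), ddy = y - (y0 + t * dy);
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        double a = r + 0.5 - d;
        if (a <= 0) continue;
        if (a > 1) a = 1;
        if (a > cov(y, x)) cov(y, x) = a;
      }
  }
  return cov;
}

// [[Rcpp::export]]
NumericMatrix cpp_ellipse_coverage(double cx, double cy, double rx,
                                   double ry, int w, int h) {
  NumericMatrix cov(h, w);
  int xa = clampi((int)std::floor(cx - rx - 1), 0, w - 1);
  int xb = clampi((int)std::ceil(cx + rx + 1), 0, w - 1);
  int ya = clampi((int)std::floor(cy - ry - 1), 0, h - 1);
  int yb = clampi((int)std::ceil(cy + ry + 1), 0, h - 1);
  double rmin = std::min(rx, ry);
  for (int x = xa; x <= xb; ++x)
    for (int y = ya; y <= yb; ++y) {
      double u = (x - cx) / rx, v = (y - cy) / ry;
      double d = (std::sqrt(u * u + v * v) - 1.0) * rmin;  // approx signed dist
      double a = 0.5 - d;
      if (a <= 0) continue;
      if (a > 1) a = 1;
      cov(y, x) = std::max(cov(y, x), a);
    }
  return cov;
}
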