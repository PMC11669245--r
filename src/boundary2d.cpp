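// Outer-boundary perimeter of a single 8-connected 2D component.
// The boundary is traced over pixel centres (Moore neighbourhood, clockwise,
// Jacob's stopping criterion), then polygonalized into maximal runs whose
// centres fit a straight strip of width < 1 px. The caller adds the +4 px
// Minkowski corner term that makes the estimate exact on axis-aligned
// rectangles. Matrix layout: (ny, nx), y fastest.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// clockwise (y axis pointing down): W, NW, N, NE, E, SE, S, SW
static const int DY[8] = {0, -1, -1, -1, 0, 1, 1, 1};
static const int DX[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

struct Pt {
  int y, x;
};

// minimal width of points perpendicular to the dominant axis; pts given as
// (u, v) with u strictly monotone increasing
static double min_strip_width(const std::vector<double>& u,
                              const std::vector<double>& v) {
  const int n = (int)u.size();
  if (n <= 2) return 0.0;
  // upper and lower hulls (monotone chain over already-sorted u)
  std::vector<int> up, lo;
  for (int i = 0; i < n; ++i) {
    while (up.size() >= 2) {
      int a = up[up.size() - 2], b = up[up.size() - 1];
      double crossv = (u[b] - u[a]) * (v[i] - v[a]) -
                      (v[b] - v[a]) * (u[i] - u[a]);
      if (crossv >= 0) up.pop_back(); else break;
    }
    up.push_back(i);
    while (lo.size() >= 2) {
      int a = lo[lo.size() - 2], b = lo[lo.size() - 1];
      double crossv = (u[b] - u[a]) * (v[i] - v[a]) -
                      (v[b] - v[a]) * (u[i] - u[a]);
      if (crossv <= 0) lo.pop_back(); else break;
    }
    lo.push_back(i);
  }
  auto spread = [&](double m) {
    double mx = -1e300, mn = 1e300;
    for (int i : up) { double r = v[i] - m * u[i]; if (r > mx) mx = r; }
    for (int i : lo) { double r = v[i] - m * u[i]; if (r < mn) mn = r; }
    // hull vertices suffice: extremes of v - m*u lie on the hulls
    for (int i : lo) { double r = v[i] - m * u[i]; if (r > mx) mx = r; }
    for (int i : up) { double r = v[i] - m * u[i]; if (r < mn) mn = r; }
    return mx - mn;
  };
  double best = 1e300;
  for (size_t k = 1; k < up.size(); ++k) {
    double du = u[up[k]] - u[up[k - 1]];
    if (du <= 0) continue;
    best = std::min(best, spread((v[up[k]] - v[up[k - 1]]) / du));
  }
  for (size_t k = 1; k < lo.size(); ++k) {
    double du = u[lo[k]] - u[lo[k - 1]];
    if (du <= 0) continue;
    best = std::min(best, spread((v[lo[k]] - v[lo[k - 1]]) / du));
  }
  if (best > 1e299) best = spread(0.0);
  return best;
}

static bool adjacent_dirs(int a, int b) {
  int d = std::abs(a - b);
  return d <= 1 || d == 7;
}

}  // namespace

// [[Rcpp::export]]
double cpp_trace_perimeter(LogicalVector mask, int ny, int nx) {
  // start: smallest linear index (topmost pixel of leftmost occupied column)
  R_xlen_t s = -1;
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    if (mask[i]) { s = i; break; }
  if (s < 0) return 0.0;
  auto at = [&](int y, int x) -> bool {
    if (y < 0 || y >= ny || x < 0 || x >= nx) return false;
    return mask[y + (R_xlen_t)ny * x];
  };
  const int sy = (int)(s % ny), sx = (int)(s / ny);

  // Moore-neighbour tracing; terminate when the first (start -> second)
  // transition recurs, so the full closed boundary is traversed exactly once
  std::vector<Pt> path;
  path.push_back({sy, sx});
  int cy = sy, cx = sx;
  int backdir = 0;  // backtrack lies to the West of the start pixel
  int p1y = -1, p1x = -1;
  const R_xlen_t maxit = 8 * (R_xlen_t)mask.size() + 16;
  R_xlen_t it = 0;
  while (it++ < maxit) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (backdir + k) % 8;
      if (at(cy + DY[d], cx + DX[d])) { found = d; break; }
    }
    if (found < 0) return 0.0;  // isolated pixel
    int py = cy, px = cx;
    int nyy = cy + DY[found], nxx = cx + DX[found];
    if (it == 1) { p1y = nyy; p1x = nxx; }
    else if (py == sy && px == sx && nyy == p1y && nxx == p1x) break;
    cy = nyy;
    cx = nxx;
    path.push_back({cy, cx});
    // new backtrack direction: from the new pixel towards the previous pixel's
    // last empty probe = direction (found - 1) from the previous pixel
    int lastEmpty = (found + 7) % 8;
    int by = py + DY[lastEmpty], bx = px + DX[lastEmpty];
    // direction index from (cy,cx) to (by,bx)
    int ddy = by - cy, ddx = bx - cx;
    backdir = 0;
    for (int d = 0; d < 8; ++d)
      if (DY[d] == ddy && DX[d] == ddx) { backdir = d; break; }
  }
  // ensure the path is closed at the start pixel
  if (path.back().y != sy || path.back().x != sx) path.push_back({sy, sx});

  const int m = (int)path.size() - 1;  // number of steps
  if (m <= 0) return 0.0;

  // greedy maximal straight runs
  auto stepdir = [&](int i) {
    int ddy = path[i + 1].y - path[i].y, ddx = path[i + 1].x - path[i].x;
    for (int d = 0; d < 8; ++d)
      if (DY[d] == ddy && DX[d] == ddx) return d;
    return -1;
  };
  double total = 0.0;
  int segStart = 0;
  int d1 = -1, d2 = -1;  // the (at most two) directions used in this run
  auto commit = [&](int endIdx) {
    double dy = path[endIdx].y - path[segStart].y;
    double dx = path[endIdx].x - path[segStart].x;
    total += std::sqrt(dy * dy + dx * dx);
  };
  for (int i = 0; i < m; ++i) {
    int d = stepdir(i);
    bool ok = true;
    int nd1 = d1, nd2 = d2;
    if (nd1 < 0) nd1 = d;
    else if (d != nd1 && nd2 < 0) {
      if (adjacent_dirs(d, nd1)) nd2 = d; else ok = false;
    } else if (d != nd1 && d != nd2) ok = false;
    if (ok && nd2 >= 0) {
      // two-direction run: check strip width over centres
      // dominant axis: the one every step advances by exactly 1
      bool xdom = (DX[nd1] != 0 && DX[nd2] != 0 && DX[nd1] == DX[nd2]);
      bool ydom = (DY[nd1] != 0 && DY[nd2] != 0 && DY[nd1] == DY[nd2]);
      if (!xdom && !ydom) ok = false;
      if (ok) {
        std::vector<double> u, v;
        const int len = i + 1 - segStart + 1;
        u.reserve(len); v.reserve(len);
        for (int j = segStart; j <= i + 1; ++j) {
          double uu = xdom ? path[j].x : path[j].y;
          double vv = xdom ? path[j].y : path[j].x;
          u.push_back(uu); v.push_back(vv);
        }
        if (u.back() < u.front())
          for (double& uu : u) uu = -uu;
        if (min_strip_width(u, v) >= 1.0 - 1e-9) ok = false;
      }
    }
    if (ok) { d1 = nd1; d2 = nd2; continue; }
    commit(i);
    segStart = i;
    d1 = d; d2 = -1;
  }
  commit(m);
  return total;
}
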