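// 3D morphology primitives: exact Euclidean distance transform with
// anisotropic spacing, connected-component labelling, plateau-aware regional
// maxima, and seeded watershed with deterministic tie-breaking.
// Arrays are (ny, nx, nz), y fastest. Ties resolve by ascending linear index.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Felzenszwalb-Huttenlocher 1D squared distance transform, sample pitch w.
// The lower envelope is built over the finite-valued parabolas only; the
// caller guarantees at least one finite entry.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT to the nearest background voxel centre; `spacing` = (dy, dx, dz).
// [[Rcpp::export]]
NumericVector cpp_edt3(LogicalVector mask, int ny, int nx, int nz,
                       NumericVector spacing) {
  NumericVector out(mask.size());
  double* o = REAL(out);
  for (R_xlen_t i = 0; i < mask.size(); ++i) o[i] = mask[i] ? INF : 0.0;
  const int ns[3] = {ny, nx, nz};
  const int strides[3] = {1, ny, ny * nx};
  for (int axis = 0; axis < 3; ++axis) {
    const int n = ns[axis];
    const int stride = strides[axis];
    const int n1 = (axis == 0) ? nx : ny;
    const int n2 = (axis == 2) ? nx : nz;
    const int s1 = (axis == 0) ? ny : 1;
    const int s2 = (axis == 2) ? ny : ny * nx;
    std::vector<double> f(n), d(n), z(n + 1);
    std::vector<int> v(n);
    for (int b = 0; b < n2; ++b)
      for (int a = 0; a < n1; ++a) {
        double* line = o + (R_xlen_t)a * s1 + (R_xlen_t)b * s2;
        bool any = false, allinf = true;
        for (int i = 0; i < n; ++i) {
          f[i] = line[(R_xlen_t)i * stride];
          if (f[i] != 0.0) any = true;
          if (f[i] != INF) allinf = false;
        }
        if (!any || allinf) continue;
        dt1d(f, d, v, z, n, spacing[axis]);
        for (int i = 0; i < n; ++i) line[(R_xlen_t)i * stride] = d[i];
      }
  }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    if (o[i] == INF) o[i] = -1.0; // whole volume foreground: flag
  return out;
}

struct NbOffsets {
  std::vector<int> dy, dx, dz;
  NbOffsets(int conn) {
    for (int z = -1; z <= 1; ++z)
      for (int x = -1; x <= 1; ++x)
        for (int y = -1; y <= 1; ++y) {
          if (y == 0 && x == 0 && z == 0) continue;
          int manh = std::abs(y) + std::abs(x) + std::abs(z);
          if (conn == 6 && manh != 1) continue;
          dy.push_back(y); dx.push_back(x); dz.push_back(z);
        }
  }
};

// Connected components; labels assigned in ascending scan order (deterministic).
// [[Rcpp::export]]
IntegerVector cpp_label3(LogicalVector mask, int ny, int nx, int nz, int conn) {
  IntegerVector out(mask.size());
  NbOffsets nb(conn);
  const int nn = (int)nb.dy.size();
  std::vector<R_xlen_t> stack;
  int lab = 0;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || out[i] != 0) continue;
    ++lab;
    out[i] = lab;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int y = (int)(cur % ny);
      int x = (int)((cur / ny) % nx);
      int z = (int)(cur / ((R_xlen_t)ny * nx));
      for (int k = 0; k < nn; ++k) {
        int yy = y + nb.dy[k], xx = x + nb.dx[k], zz = z + nb.dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
        if (mask[j] && out[j] == 0) { out[j] = lab; stack.push_back(j); }
      }
    }
  }
  out.attr("n_labels") = lab;
  return out;
}

// Regional maxima of `x` restricted to `mask` (26-connectivity, plateau-aware).
// [[Rcpp::export]]
LogicalVector cpp_regmax3(NumericVector x, LogicalVector mask,
                          int ny, int nx, int nz) {
  LogicalVector out(x.size());
  std::vector<char> visited(x.size(), 0);
  NbOffsets nb(26);
  const int nn = (int)nb.dy.size();
  std::vector<R_xlen_t> plateau, stack;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    if (!mask[i] || visited[i]) continue;
    const double val = x[i];
    bool is_max = true;
    plateau.clear();
    stack.clear();
    stack.push_back(i);
    visited[i] = 1;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      plateau.push_back(cur);
      int y = (int)(cur % ny);
      int xx0 = (int)((cur / ny) % nx);
      int z = (int)(cur / ((R_xlen_t)ny * nx));
      for (int k = 0; k < nn; ++k) {
        int yy = y + nb.dy[k], xx = xx0 + nb.dx[k], zz = z + nb.dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
        if (!mask[j]) continue;
        if (x[j] > val) is_max = false;
        else if (x[j] == val && !visited[j]) {
          visited[j] = 1;
          stack.push_back(j);
        }
      }
    }
    if (is_max)
      for (R_xlen_t p : plateau) out[p] = true;
  }
  return out;
}

struct WsEntry {
  double elev;
  R_xlen_t seq;  // insertion order: FIFO within equal elevation
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.seq > b.seq;
  }
};

// Marker-based watershed of `elev` restricted to `mask` (26-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_watershed3(NumericVector elev, IntegerVector markers,
                             LogicalVector mask, int ny, int nx, int nz) {
  IntegerVector out(elev.size());
  NbOffsets nb(26);
  const int nn = (int)nb.dy.size();
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  R_xlen_t seq = 0;
  for (R_xlen_t i = 0; i < elev.size(); ++i) {
    if (markers[i] > 0 && mask[i]) {
      out[i] = markers[i];
      pq.push({elev[i], seq++, i, markers[i]});
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int y = (int)(e.idx % ny);
    int x0 = (int)((e.idx / ny) % nx);
    int z = (int)(e.idx / ((R_xlen_t)ny * nx));
    for (int k = 0; k < nn; ++k) {
      int yy = y + nb.dy[k], xx = x0 + nb.dx[k], zz = z + nb.dz[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
      if (!mask[j] || out[j] != 0) continue;
      out[j] = e.label;
      pq.push({elev[j], seq++, j, e.label});
    }
  }
  return out;
}
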