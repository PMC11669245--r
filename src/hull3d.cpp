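// Quickhull in 3D, returning hull volume, surface area and facet count.
// Facets are oriented against a fixed interior point, so volume is the sum of
// positively-signed tetrahedra. Near-coplanar inputs return volume 0 with a
// degenerate flag; callers decide how to regularize.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
static inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Facet {
  int v[3];
  int nb[3];        // neighbor across edge (v[k], v[(k+1)%3])
  Vec3 n;           // unit outward normal
  double off;       // plane offset: dot(n, p) = off
  std::vector<int> outside;
  bool alive = true;
};

struct Hull {
  const std::vector<Vec3>& P;
  std::vector<Facet> F;
  Vec3 interior;
  double eps;

  Hull(const std::vector<Vec3>& pts) : P(pts) {}

  double dist(int f, int p) const { return dot(F[f].n, P[p]) - F[f].off; }

  void set_plane(Facet& f) {
    Vec3 nn = cross(sub(P[f.v[1]], P[f.v[0]]), sub(P[f.v[2]], P[f.v[0]]));
    double ln = norm(nn);
    if (ln < 1e-300) ln = 1.0;
    f.n = {nn.x / ln, nn.y / ln, nn.z / ln};
    f.off = dot(f.n, P[f.v[0]]);
    // orient away from the interior point
    if (dot(f.n, interior) - f.off > 0) {
      std::swap(f.v[1], f.v[2]);
      std::swap(f.nb[0], f.nb[2]);  // edges (01),(12),(20) -> (02),(21),(10)
      f.n = {-f.n.x, -f.n.y, -f.n.z};
      f.off = -f.off;
    }
  }

  bool build();
};

bool Hull::build() {
  const int n = (int)P.size();
  if (n < 4) return false;
  double scale = 0.0;
  for (const Vec3& p : P)
    scale = std::max({scale, std::fabs(p.x), std::fabs(p.y), std::fabs(p.z)});
  eps = 1e-9 * std::max(scale, 1.0);

  // initial extremes
  int ix[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[ix[0]].x) ix[0] = i;
    if (P[i].x > P[ix[1]].x) ix[1] = i;
    if (P[i].y < P[ix[2]].y) ix[2] = i;
    if (P[i].y > P[ix[3]].y) ix[3] = i;
    if (P[i].z < P[ix[4]].z) ix[4] = i;
    if (P[i].z > P[ix[5]].z) ix[5] = i;
  }
  int a = -1, b = -1;
  double best = -1.0;
  for (int i = 0; i < 6; ++i)
    for (int j = i + 1; j < 6; ++j) {
      double d = norm(sub(P[ix[i]], P[ix[j]]));
      if (d > best) { best = d; a = ix[i]; b = ix[j]; }
    }
  if (best < eps) return false;
  // farthest from line ab
  int c = -1;
  best = -1.0;
  Vec3 ab = sub(P[b], P[a]);
  double lab = norm(ab);
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(ab, sub(P[i], P[a]))) / lab;
    if (d > best) { best = d; c = i; }
  }
  if (best < eps) return false;
  // farthest from plane abc
  Vec3 nrm = cross(ab, sub(P[c], P[a]));
  double ln = norm(nrm);
  nrm = {nrm.x / ln, nrm.y / ln, nrm.z / ln};
  int d4 = -1;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[a])));
    if (d > best) { best = d; d4 = i; }
  }
  if (best < eps) return false;

  interior = {(P[a].x + P[b].x + P[c].x + P[d4].x) / 4.0,
              (P[a].y + P[b].y + P[c].y + P[d4].y) / 4.0,
              (P[a].z + P[b].z + P[c].z + P[d4].z) / 4.0};

  // four facets of the initial tetrahedron
  int vs[4] = {a, b, c, d4};
  int tri[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
  F.resize(4);
  for (int f = 0; f < 4; ++f) {
    F[f].v[0] = vs[tri[f][0]];
    F[f].v[1] = vs[tri[f][1]];
    F[f].v[2] = vs[tri[f][2]];
    for (int k = 0; k < 3; ++k) F[f].nb[k] = -1;
    set_plane(F[f]);
  }
  // adjacency by shared-edge matching
  auto key = [](int u, int v) {
    return std::make_pair(std::min(u, v), std::max(u, v));
  };
  std::map<std::pair<int, int>, std::pair<int, int>> edges;
  for (int f = 0; f < 4; ++f)
    for (int k = 0; k < 3; ++k) {
      auto e = key(F[f].v[k], F[f].v[(k + 1) % 3]);
      auto it = edges.find(e);
      if (it == edges.end()) edges[e] = {f, k};
      else {
        F[f].nb[k] = it->second.first;
        F[it->second.first].nb[it->second.second] = f;
      }
    }

  // initial outside sets
  for (int i = 0; i < n; ++i) {
    if (i == a || i == b || i == c || i == d4) continue;
    int bf = -1;
    double bd = eps;
    for (int f = 0; f < 4; ++f) {
      double d = dist(f, i);
      if (d > bd) { bd = d; bf = f; }
    }
    if (bf >= 0) F[bf].outside.push_back(i);
  }

  std::vector<int> pending;
  for (int f = 0; f < 4; ++f)
    if (!F[f].outside.empty()) pending.push_back(f);

  std::vector<int> visible, stack;
  std::vector<char> seen;
  while (!pending.empty()) {
    int f0 = pending.back();
    pending.pop_back();
    if (!F[f0].alive || F[f0].outside.empty()) continue;
    // farthest point of this facet's outside set
    int p = -1;
    double bd = -1.0;
    for (int q : F[f0].outside) {
      double d = dist(f0, q);
      if (d > bd) { bd = d; p = q; }
    }
    // visible set (BFS)
    visible.clear();
    stack.clear();
    seen.assign(F.size(), 0);
    stack.push_back(f0);
    seen[f0] = 1;
    while (!stack.empty()) {
      int f = stack.back(); stack.pop_back();
      visible.push_back(f);
      for (int k = 0; k < 3; ++k) {
        int g = F[f].nb[k];
        if (g < 0 || seen[g] || !F[g].alive) continue;
        if (dist(g, p) > eps) { seen[g] = 1; stack.push_back(g); }
      }
    }
    // horizon edges: (edge of visible facet, hidden neighbor, neighbor slot)
    struct HEdge { int u, v, g, gk; };
    std::vector<HEdge> horizon;
    for (int f : visible)
      for (int k = 0; k < 3; ++k) {
        int g = F[f].nb[k];
        if (g < 0 || seen[g]) continue;
        int gk = -1;
        for (int m = 0; m < 3; ++m)
          if (F[g].nb[m] == f) gk = m;
        horizon.push_back({F[f].v[k], F[f].v[(k + 1) % 3], g, gk});
      }
    // collect points to redistribute
    std::vector<int> orphans;
    for (int f : visible) {
      for (int q : F[f].outside)
        if (q != p) orphans.push_back(q);
      F[f].alive = false;
      F[f].outside.clear();
    }
    // build new facets
    std::map<std::pair<int, int>, std::pair<int, int>> emap;
    std::vector<int> fresh;
    for (const HEdge& he : horizon) {
      Facet nf;
      nf.v[0] = he.u; nf.v[1] = he.v; nf.v[2] = p;
      nf.nb[0] = nf.nb[1] = nf.nb[2] = -1;
      set_plane(nf);
      int id = (int)F.size();
      F.push_back(nf);
      fresh.push_back(id);
      // link across the horizon edge
      int slot = -1;
      for (int k = 0; k < 3; ++k) {
        int u = F[id].v[k], v = F[id].v[(k + 1) % 3];
        if ((u == he.u && v == he.v) || (u == he.v && v == he.u)) slot = k;
      }
      F[id].nb[slot] = he.g;
      F[he.g].nb[he.gk] = id;
      // link new-new edges (those touching p)
      for (int k = 0; k < 3; ++k) {
        if (k == slot) continue;
        auto e = key(F[id].v[k], F[id].v[(k + 1) % 3]);
        auto it = emap.find(e);
        if (it == emap.end()) emap[e] = {id, k};
        else {
          F[id].nb[k] = it->second.first;
          F[it->second.first].nb[it->second.second] = id;
        }
      }
    }
    // redistribute orphans
    for (int q : orphans) {
      int bf = -1;
      double bq = eps;
      for (int id : fresh) {
        double d = dist(id, q);
        if (d > bq) { bq = d; bf = id; }
      }
      if (bf >= 0) F[bf].outside.push_back(q);
    }
    for (int id : fresh)
      if (!F[id].outside.empty()) pending.push_back(id);
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_hull3(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<Vec3> P(n);
  for (int i = 0; i < n; ++i) P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  Hull h(P);
  if (!h.build()) {
    return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                        _["n_facets"] = 0L, _["degenerate"] = true);
  }
  double vol = 0.0, area = 0.0;
  int nf = 0;
  for (const Facet& f : h.F) {
    if (!f.alive) continue;
    ++nf;
    Vec3 a = P[f.v[0]], b = P[f.v[1]], c = P[f.v[2]];
    Vec3 cr = cross(sub(b, a), sub(c, a));
    area += 0.5 * norm(cr);
    Vec3 ar = sub(a, h.interior), br = sub(b, h.interior),
         cr2 = sub(c, h.interior);
    vol += std::fabs(dot(ar, cross(br, cr2))) / 6.0;
  }
  return List::create(_["volume"] = vol, _["area"] = area,
                      _["n_facets"] = nf, _["degenerate"] = false);
}
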