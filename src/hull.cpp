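#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull, volume only. Points are neuron node
// coordinates (tens to a few thousand), so the O(n * faces) incremental
// scheme is more than fast enough. Degenerate inputs (all points
// collinear or coplanar) have zero volume by convention.

namespace {

struct V3 {
  double x, y, z;
};

inline V3 sub(const V3 &a, const V3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;   // vertex indices, counter-clockwise seen from outside
  V3 n;          // outward normal (not normalized)
  double off;    // n . vertex
  bool alive;
};

inline double face_dist(const Face &f, const V3 &p) {
  return dot(f.n, p) - f.off;
}

} // namespace

// [[Rcpp::export(name = ".convex_hull_volume_cpp")]]
double convex_hull_volume_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<V3> p(n);
  double diam = 0.0;
  for (int i = 0; i < n; ++i) p[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  // bounding-box diagonal sets the degeneracy tolerance scale
  double lo[3] = {p[0].x, p[0].y, p[0].z}, hi[3] = {p[0].x, p[0].y, p[0].z};
  for (int i = 1; i < n; ++i) {
    lo[0] = std::min(lo[0], p[i].x); hi[0] = std::max(hi[0], p[i].x);
    lo[1] = std::min(lo[1], p[i].y); hi[1] = std::max(hi[1], p[i].y);
    lo[2] = std::min(lo[2], p[i].z); hi[2] = std::max(hi[2], p[i].z);
  }
  diam = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                   (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                   (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (diam <= 0.0) return 0.0;
  const double tol = 1e-10 * diam;

  // initial simplex: two extreme points, then max-area, then max-volume
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d = norm(sub(p[i], p[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= tol) return 0.0;
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double d = norm(cross(sub(p[i1], p[i0]), sub(p[i], p[i0])));
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0 || best <= tol * diam) return 0.0;  // collinear
  V3 nrm = cross(sub(p[i1], p[i0]), sub(p[i2], p[i0]));
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d = std::fabs(dot(nrm, sub(p[i], p[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0 || best <= tol * diam * diam) return 0.0;  // coplanar

  V3 inner = {(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4.0,
              (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4.0,
              (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4.0};

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    f.n = cross(sub(p[b], p[a]), sub(p[c], p[a]));
    f.off = dot(f.n, p[a]);
    if (face_dist(f, inner) > 0) {  // flip to make normal outward
      std::swap(f.b, f.c);
      f.n = cross(sub(p[f.b], p[f.a]), sub(p[f.c], p[f.a]));
      f.off = dot(f.n, p[f.a]);
    }
    f.alive = true;
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    // faces visible from p[i]
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (face_dist(faces[f], p[i]) > tol * norm(faces[f].n)) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon: directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int, int>, int> edge_count;
    for (int f : vis) {
      const Face &F = faces[f];
      int e[3][2] = {{F.a, F.b}, {F.b, F.c}, {F.c, F.a}};
      for (auto &ed : e) edge_count[{ed[0], ed[1]}]++;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto &kv : edge_count) {
      auto rev = std::make_pair(kv.first.second, kv.first.first);
      if (edge_count.find(rev) == edge_count.end()) horizon.push_back(kv.first);
    }
    for (int f : vis) faces[f].alive = false;
    for (auto &ed : horizon) add_face(ed.first, ed.second, i);
  }

  double vol = 0.0;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    // signed tetra (inner, a, b, c); orientation makes each term positive
    vol += std::fabs(dot(sub(p[f.a], inner),
                         cross(sub(p[f.b], inner), sub(p[f.c], inner)))) / 6.0;
  }
  return vol;
}
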