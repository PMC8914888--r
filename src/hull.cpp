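#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull returning facet half-spaces.
// For interior points x: dot(normal, x) <= offset for every facet
// (normals unit length, pointing outward).

struct Vec3 {
  double x, y, z;
};
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm3(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;
  Vec3 n;     // outward unit normal
  double d;   // offset: dot(n, x) <= d inside
  bool alive;
};

// [[Rcpp::export]]
List convhull3_facets_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<Vec3> P(n);
  double scale = 1e-12;
  for (int i = 0; i < n; ++i) {
    P[i] = Vec3{pts(i, 0), pts(i, 1), pts(i, 2)};
  }
  double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
  double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    double c[3] = {P[i].x, P[i].y, P[i].z};
    for (int a = 0; a < 3; ++a) {
      if (c[a] < mn[a]) mn[a] = c[a];
      if (c[a] > mx[a]) mx[a] = c[a];
    }
  }
  for (int a = 0; a < 3; ++a) scale = std::max(scale, mx[a] - mn[a]);
  const double eps = 1e-9 * scale;   // degeneracy tolerance
  const double veps = 1e-9 * scale;  // strict visibility tolerance

  std::string err = "";
  if (n < 4) err = "need at least 4 points for a 3D hull";

  // initial tetrahedron: farthest pair, then farthest from line, then plane
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  if (err.empty()) {
    double best = eps;
    for (int i = 1; i < n; ++i) {
      double d = norm3(sub(P[i], P[i0]));
      if (d > best) { best = d; i1 = i; }
    }
    if (i1 < 0) err = "all points coincide";
  }
  if (err.empty()) {
    Vec3 e = sub(P[i1], P[i0]);
    double best = eps;
    for (int i = 0; i < n; ++i) {
      double d = norm3(cross(e, sub(P[i], P[i0]))) / norm3(e);
      if (d > best) { best = d; i2 = i; }
    }
    if (i2 < 0) err = "points are collinear";
  }
  Vec3 n0{0, 0, 0};
  if (err.empty()) {
    n0 = cross(sub(P[i1], P[i0]), sub(P[i2], P[i0]));
    double nn = norm3(n0);
    double best = eps;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dot(n0, sub(P[i], P[i0]))) / nn;
      if (d > best) { best = d; i3 = i; }
    }
    if (i3 < 0) err = "points are coplanar";
  }
  if (!err.empty())
    return List::create(_["ok"] = false, _["message"] = err);

  Vec3 interior{(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Vec3 nn = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    double len = norm3(nn);
    if (len < eps * eps) return; // degenerate sliver, skip
    nn.x /= len; nn.y /= len; nn.z /= len;
    double d = dot(nn, P[a]);
    if (dot(nn, interior) > d) { // flip outward
      nn.x = -nn.x; nn.y = -nn.y; nn.z = -nn.z;
      d = -d;
      int t = b; b = c; c = t;
    }
    faces.push_back(Face{a, b, c, nn, d, true});
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (dot(faces[f].n, P[p]) - faces[f].d > veps) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon = edges used by exactly one visible face
    std::vector<std::pair<int, int> > edges;
    for (size_t k = 0; k < vis.size(); ++k) {
      const Face &f = faces[vis[k]];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int j = 0; j < 3; ++j) {
        int u = std::min(e[j][0], e[j][1]), v = std::max(e[j][0], e[j][1]);
        edges.push_back(std::make_pair(u, v));
      }
    }
    std::sort(edges.begin(), edges.end());
    for (size_t k = 0; k < vis.size(); ++k) faces[vis[k]].alive = false;
    size_t k = 0;
    while (k < edges.size()) {
      size_t j = k;
      while (j < edges.size() && edges[j] == edges[k]) ++j;
      if (j - k == 1) add_face(edges[k].first, edges[k].second, p);
      k = j;
    }
  }

  int nf = 0;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) ++nf;
  NumericMatrix normals(nf, 3);
  NumericVector offsets(nf);
  int r = 0;
  for (size_t f = 0; f < faces.size(); ++f) {
    if (!faces[f].alive) continue;
    normals(r, 0) = faces[f].n.x;
    normals(r, 1) = faces[f].n.y;
    normals(r, 2) = faces[f].n.z;
    offsets[r] = faces[f].d;
    ++r;
  }
  return List::create(_["ok"] = true, _["normals"] = normals,
                      _["offsets"] = offsets, _["scale"] = scale);
}
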