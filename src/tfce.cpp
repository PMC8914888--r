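#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static int build_offsets(int conn, int off[26][3]) {
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (a == 0) continue;
        if (conn == 6 && a > 1) continue;
        if (conn == 18 && a > 2) continue;
        off[m][0] = dx; off[m][1] = dy; off[m][2] = dz;
        ++m;
      }
  return m;
}

// Connected-component labeling of a binary volume (labels 1..K in scan order).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int off[26][3];
  int m = build_offsets(conn, off);
  std::vector<int> stack;
  int next = 0;
  for (int v = 0; v < n; ++v) {
    if (!mask[v] || lab[v]) continue;
    ++next;
    lab[v] = next;
    stack.push_back(v);
    while (!stack.empty()) {
      int u = stack.back();
      stack.pop_back();
      int x = u % nx, y = (u / nx) % ny, z = u / (nx * ny);
      for (int k = 0; k < m; ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && !lab[w]) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// Threshold-free cluster enhancement of a NON-NEGATIVE statistic map:
// out(v) = sum over thresholds h = dh, 2dh, ... of e_h(v)^E * h^H * dh,
// where e_h(v) is the size of the supra-threshold cluster containing v.
// Implemented by sweeping thresholds downward with a union-find whose
// roots carry lazily accumulated per-cluster increments (value of a voxel
// = sum of increments along its path to the root), so each threshold only
// touches newly activated voxels and the current cluster roots.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims, double dh,
                       double E, double H, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n, 0.0);
  double hmax = 0.0;
  for (int v = 0; v < n; ++v)
    if (stat[v] > hmax) hmax = stat[v];
  if (hmax <= 0.0 || dh <= 0.0) return out;

  int off[26][3];
  const int m = build_offsets(conn, off);

  std::vector<int> order;
  order.reserve(n);
  for (int v = 0; v < n; ++v)
    if (stat[v] >= dh) order.push_back(v);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(n, -1), csize(n, 0);
  std::vector<double> delta(n, 0.0);
  std::vector<int> roots;
  roots.reserve(64);

  auto find = [&](int v) {
    while (parent[v] != v) v = parent[v];
    return v;
  };

  const int K = (int)std::ceil(hmax / dh);
  size_t ptr = 0;
  for (int k = K; k >= 1; --k) {
    double h = k * dh;
    while (ptr < order.size() && stat[order[ptr]] >= h) {
      int v = order[ptr++];
      parent[v] = v;
      csize[v] = 1;
      delta[v] = 0.0;
      roots.push_back(v);
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int j = 0; j < m; ++j) {
        int xx = x + off[j][0], yy = y + off[j][1], zz = z + off[j][2];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (parent[w] < 0) continue; // not yet activated
        int rv = find(v), rw = find(w);
        if (rv == rw) continue;
        if (csize[rv] < csize[rw]) std::swap(rv, rw);
        // attach rw under rv; correct rw's subtree for rv's past increments
        parent[rw] = rv;
        delta[rw] -= delta[rv];
        csize[rv] += csize[rw];
      }
    }
    // add this threshold's increment to every live cluster root
    if (!roots.empty()) {
      size_t keep = 0;
      double hH = std::pow(h, H) * dh;
      for (size_t i = 0; i < roots.size(); ++i) {
        int r = roots[i];
        if (parent[r] != r) continue; // absorbed by a union
        delta[r] += std::pow((double)csize[r], E) * hH;
        roots[keep++] = r;
      }
      roots.resize(keep);
    }
  }

  // resolve each active voxel: sum of deltas along its path to the root
  for (size_t i = 0; i < order.size(); ++i) {
    int v = order[i];
    double s = 0.0;
    int u = v;
    while (true) {
      s += delta[u];
      if (parent[u] == u) break;
      u = parent[u];
    }
    out[v] = s;
  }
  return out;
}
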