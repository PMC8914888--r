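#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// wrap to (-pi, pi], half-open at -pi
static inline double wrap_pi(double x) {
  double y = std::fmod(x + M_PI, 2.0 * M_PI);
  if (y <= 0.0) y += 2.0 * M_PI;
  return y - M_PI;
}

struct Cand {
  double q;      // quality of the candidate voxel
  int idx;       // linear index (0-based)
  double ref;    // unwrapped value of the already-processed neighbour
};

// higher quality first; ties broken by LOWER linear index for determinism
struct CandCmp {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.q != b.q) return a.q < b.q;
    return a.idx > b.idx;
  }
};

// Quality-guided ("best path") 3D phase unwrapping by region growing.
// Quality = negated sum of squared wrapped second differences of the wrapped
// phase along the three axes; region grows through 6-connected neighbours,
// always unwrapping the highest-quality candidate next.  Each connected
// component of the mask is seeded independently (its own global 2*pi*k).
// [[Rcpp::export]]
NumericVector unwrap_bestpath_cpp(NumericVector phase, LogicalVector mask,
                                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if ((int)phase.size() != n || (int)mask.size() != n)
    stop("phase/mask size does not match dims");

  NumericVector out(clone(phase));
  std::vector<char> processed(n, 0);
  std::vector<double> qual(n, 0.0);

  const double TWO_PI = 2.0 * M_PI;
  // second differences
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = x + nx * (y + ny * z);
        if (!mask[v]) continue;
        double s = 0.0;
        int c[3] = {x, y, z};
        int lim[3] = {nx, ny, nz};
        int stride[3] = {1, nx, nx * ny};
        for (int ax = 0; ax < 3; ++ax) {
          if (c[ax] > 0 && c[ax] < lim[ax] - 1) {
            int vp = v + stride[ax], vm = v - stride[ax];
            if (mask[vp] && mask[vm]) {
              double d = wrap_pi(phase[vp] - phase[v]) -
                         wrap_pi(phase[v] - phase[vm]);
              s += d * d;
            }
          }
        }
        qual[v] = -s;
      }

  // seeds ordered by quality (desc), index (asc)
  std::vector<int> order;
  order.reserve(n);
  for (int v = 0; v < n; ++v)
    if (mask[v]) order.push_back(v);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (qual[a] != qual[b]) return qual[a] > qual[b];
    return a < b;
  });

  std::priority_queue<Cand, std::vector<Cand>, CandCmp> pq;
  size_t seed_ptr = 0;
  int remaining = (int)order.size();

  while (remaining > 0) {
    // next seed: best unprocessed voxel (new connected component)
    while (seed_ptr < order.size() && processed[order[seed_ptr]]) ++seed_ptr;
    if (seed_ptr >= order.size()) break;
    int s = order[seed_ptr];
    pq.push(Cand{qual[s], s, phase[s]}); // seed keeps its wrapped value

    while (!pq.empty()) {
      Cand c = pq.top();
      pq.pop();
      int v = c.idx;
      if (processed[v]) continue;
      double pw = phase[v];
      out[v] = pw + TWO_PI * std::round((c.ref - pw) / TWO_PI);
      processed[v] = 1;
      --remaining;

      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int u = xx + nx * (yy + ny * zz);
        if (mask[u] && !processed[u]) pq.push(Cand{qual[u], u, out[v]});
      }
    }
  }
  return out;
}
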