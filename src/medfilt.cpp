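#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3x3x3 median filter with edge replication; edge-preserving denoiser core.
// [[Rcpp::export]]
NumericVector median3_cpp(NumericVector vol, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve(27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = std::min(std::max(x + dx, 0), nx - 1);
              int yy = std::min(std::max(y + dy, 0), ny - 1);
              int zz = std::min(std::max(z + dz, 0), nz - 1);
              buf.push_back(vol[xx + nx * (yy + ny * zz)]);
            }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.end());
        out[x + nx * (y + ny * z)] = buf[13];
      }
  return out;
}
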