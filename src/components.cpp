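#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Connected-component labeling of a 3-D mask, 6- or 26-connectivity.
// Labels are 1..N in first-encounter (scan) order; background stays 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t n = nxy * nz;
  IntegerVector labels(n, 0);

  std::vector<int> dx, dy, dz;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
  const int nn = (int)dx.size();

  int next_label = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t idx = q.front();
      q.pop();
      int iz = (int)(idx / nxy);
      R_xlen_t rem = idx - (R_xlen_t)iz * nxy;
      int iy = (int)(rem / nx);
      int ix = (int)(rem - (R_xlen_t)iy * nx);
      for (int t = 0; t < nn; ++t) {
        int jx = ix + dx[t], jy = iy + dy[t], jz = iz + dz[t];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        R_xlen_t jdx = (R_xlen_t)jz * nxy + (R_xlen_t)jy * nx + jx;
        if (mask[jdx] && labels[jdx] == 0) {
          labels[jdx] = next_label;
          q.push(jdx);
        }
      }
    }
  }
  return labels;
}
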