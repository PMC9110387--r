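#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// First-order fast marching on a regular grid with isotropic spacing h.
// Solves |grad u| = f (f = slowness = 1/speed) with the Godunov upwind
// discretization and a 6-neighborhood. Voxels outside `domain` are never
// visited; unreachable domain voxels stay +Inf.
// [[Rcpp::export]]
NumericVector fast_marching_cpp(NumericVector slowness, LogicalVector source,
                                LogicalVector domain, IntegerVector dims,
                                double h) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;

  NumericVector u(n, INF);
  std::vector<char> state(n, 0); // 0 far, 1 trial, 2 frozen

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (source[i]) {
      u[i] = 0.0;
      state[i] = 1;
      heap.push(QE(0.0, i));
    }
  }

  // Godunov update at voxel idx from frozen neighbors
  auto solve_at = [&](R_xlen_t idx, int ix, int iy, int iz) -> double {
    double a[3];
    int m = 0;
    // axis minima among frozen neighbors
    double v;
    // x
    v = INF;
    if (ix > 0 && state[idx - 1] == 2) v = u[idx - 1];
    if (ix < nx - 1 && state[idx + 1] == 2) v = std::min(v, (double)u[idx + 1]);
    if (v < INF) a[m++] = v;
    // y
    v = INF;
    if (iy > 0 && state[idx - nx] == 2) v = u[idx - nx];
    if (iy < ny - 1 && state[idx + nx] == 2) v = std::min(v, (double)u[idx + nx]);
    if (v < INF) a[m++] = v;
    // z
    v = INF;
    if (iz > 0 && state[idx - nxy] == 2) v = u[idx - nxy];
    if (iz < nz - 1 && state[idx + nxy] == 2) v = std::min(v, (double)u[idx + nxy]);
    if (v < INF) a[m++] = v;
    if (m == 0) return INF;

    std::sort(a, a + m);
    double rhs = h * slowness[idx];
    // try with increasing number of axes; accept the largest consistent root
    double best = a[0] + rhs;
    if (m >= 2 && best > a[1]) {
      double s = a[0] + a[1], q = a[0] * a[0] + a[1] * a[1];
      double disc = s * s - 2.0 * (q - rhs * rhs);
      if (disc >= 0) {
        double r = (s + std::sqrt(disc)) / 2.0;
        if (r > a[1]) best = r;
        if (m >= 3 && r > a[2]) {
          double s3 = s + a[2], q3 = q + a[2] * a[2];
          double disc3 = s3 * s3 - 3.0 * (q3 - rhs * rhs);
          if (disc3 >= 0) {
            double r3 = (s3 + std::sqrt(disc3)) / 3.0;
            if (r3 > a[2]) best = r3;
          }
        }
      }
    }
    return best;
  };

  while (!heap.empty()) {
    QE top = heap.top();
    heap.pop();
    R_xlen_t idx = top.second;
    if (state[idx] == 2) continue;       // stale entry
    if (top.first > u[idx]) continue;    // superseded
    state[idx] = 2;
    int iz = (int)(idx / nxy);
    R_xlen_t rem = idx - (R_xlen_t)iz * nxy;
    int iy = (int)(rem / nx);
    int ix = (int)(rem - (R_xlen_t)iy * nx);

    const int dx[6] = {-1, 1, 0, 0, 0, 0};
    const int dy[6] = {0, 0, -1, 1, 0, 0};
    const int dz[6] = {0, 0, 0, 0, -1, 1};
    for (int q = 0; q < 6; ++q) {
      int jx = ix + dx[q], jy = iy + dy[q], jz = iz + dz[q];
      if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
        continue;
      R_xlen_t jdx = (R_xlen_t)jz * nxy + (R_xlen_t)jy * nx + jx;
      if (!domain[jdx] || state[jdx] == 2) continue;
      double cand = solve_at(jdx, jx, jy, jz);
      if (cand < u[jdx]) {
        u[jdx] = cand;
        state[jdx] = 1;
        heap.push(QE(cand, jdx));
      }
    }
  }
  return u;
}
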