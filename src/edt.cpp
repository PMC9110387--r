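#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite sentinel standing in for "no seed on this line yet".
// Squared distances on any realistic grid are far below this, and keeping
// it finite keeps the parabola-intersection arithmetic well defined.
static const double BIG = 1e30;

// 1-D lower envelope of parabolas (exact squared distance transform),
// sample positions i*h.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, double h,
                 int n, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double xq = q * h;
    double s;
    while (true) {
      double xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double x = q * h;
    while (z[j + 1] < x) ++j;
    double dx = x - v[j] * h;
    d[q] = dx * dx + f[v[j]];
  }
}

// Exact squared Euclidean distance (mm^2) from every voxel to the nearest
// voxel where mask is TRUE. Column-major dims (nx, ny, nz). Voxels farther
// than any seed in an empty mask come back >= 1e29 (caller treats as Inf).
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, spacing[0], nx, v, z);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, spacing[1], ny, v, z);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // along z
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + k * nxy];
      dt1d(f, d, spacing[2], nz, v, z);
      for (int k = 0; k < nz; ++k) out[base + k * nxy] = d[k];
    }
  return out;
}
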