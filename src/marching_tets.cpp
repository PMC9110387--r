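#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Surface extraction at a level set of a scalar grid by marching
// tetrahedra. Each cube is split into the six Kuhn tetrahedra around its
// main diagonal; the split is mirror-consistent across shared cube faces,
// so the output is a conforming (crack-free) triangle surface. Interface
// vertices are placed by linear interpolation along tetrahedron edges and
// welded through a global edge map. Triangles are wound so that their
// normals point toward the positive side of (field - level), i.e. outward
// for a signed distance field.

struct Key {
  uint64_t k;
  bool operator==(const Key& o) const { return k == o.k; }
};
struct KeyHash {
  size_t operator()(const Key& a) const { return std::hash<uint64_t>()(a.k); }
};

// [[Rcpp::export]]
List marching_tets_cpp(NumericVector field, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;

  // corner offsets of a cube, binary order (x fastest)
  const int co[8][3] = {{0,0,0},{1,0,0},{0,1,0},{1,1,0},
                        {0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  // Kuhn tetrahedra: permutation paths 0 -> 7 through corner indices
  const int tets[6][4] = {
    {0,1,3,7},{0,1,5,7},{0,2,3,7},{0,2,6,7},{0,4,5,7},{0,4,6,7}};

  std::vector<double> vx, vy, vz;
  std::vector<int> t0, t1, t2;
  std::unordered_map<Key, int, KeyHash> edge_map;

  auto corner_index = [&](int ix, int iy, int iz) -> uint64_t {
    return (uint64_t)iz * (uint64_t)nxy + (uint64_t)iy * nx + ix;
  };

  auto interp_vertex = [&](uint64_t ca, uint64_t cb, double va, double vb,
                           int ax, int ay, int az, int bx, int by, int bz) -> int {
    uint64_t lo = ca < cb ? ca : cb, hi = ca < cb ? cb : ca;
    Key key{(lo << 32) | hi};
    auto it = edge_map.find(key);
    if (it != edge_map.end()) return it->second;
    double t = (level - va) / (vb - va);
    if (t < 0) t = 0;
    if (t > 1) t = 1;
    double px = origin[0] + (ax + t * (bx - ax)) * spacing[0];
    double py = origin[1] + (ay + t * (by - ay)) * spacing[1];
    double pz = origin[2] + (az + t * (bz - az)) * spacing[2];
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    edge_map[key] = id;
    return id;
  };

  for (int iz = 0; iz < nz - 1; ++iz)
    for (int iy = 0; iy < ny - 1; ++iy)
      for (int ix = 0; ix < nx - 1; ++ix) {
        double val[8];
        int gx[8], gy[8], gz[8];
        uint64_t cid[8];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          gx[c] = ix + co[c][0]; gy[c] = iy + co[c][1]; gz[c] = iz + co[c][2];
          cid[c] = corner_index(gx[c], gy[c], gz[c]);
          val[c] = field[cid[c]] - level;
          if (val[c] < 0) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int tt = 0; tt < 6; ++tt) {
          const int* tv = tets[tt];
          int inside[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            if (val[tv[c]] < 0) inside[nin++] = c;
          if (nin == 0 || nin == 4) continue;

          // collect crossing-edge vertices
          int verts[4];
          int nverts = 0;
          int outside[4], nout = 0;
          for (int c = 0; c < 4; ++c)
            if (val[tv[c]] >= 0) outside[nout++] = c;
          auto ev = [&](int ci, int cj) -> int {
            int a = tv[ci], b = tv[cj];
            return interp_vertex(cid[a], cid[b], val[a], val[b],
                                 gx[a], gy[a], gz[a], gx[b], gy[b], gz[b]);
          };
          if (nin == 1) {
            int i0 = inside[0];
            for (int c = 0; c < 4; ++c)
              if (c != i0) verts[nverts++] = ev(i0, c);
            t0.push_back(verts[0]); t1.push_back(verts[1]); t2.push_back(verts[2]);
          } else if (nin == 3) {
            int o0 = outside[0];
            for (int c = 0; c < 4; ++c)
              if (c != o0) verts[nverts++] = ev(c, o0);
            t0.push_back(verts[0]); t1.push_back(verts[1]); t2.push_back(verts[2]);
          } else { // nin == 2: quad
            int i0 = inside[0], i1 = inside[1];
            int o0 = outside[0], o1 = outside[1];
            int v00 = ev(i0, o0), v01 = ev(i0, o1);
            int v11 = ev(i1, o1), v10 = ev(i1, o0);
            t0.push_back(v00); t1.push_back(v01); t2.push_back(v11);
            t0.push_back(v00); t1.push_back(v11); t2.push_back(v10);
          }
        }
      }

  // Orient every triangle so its normal points toward the positive field
  // side, using the local field gradient at the triangle centroid.
  R_xlen_t ntri = t0.size();
  auto field_at = [&](double wx, double wy, double wz) -> double {
    // trilinear sample in index space, clamped
    double fx = (wx - origin[0]) / spacing[0];
    double fy = (wy - origin[1]) / spacing[1];
    double fz = (wz - origin[2]) / spacing[2];
    int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy), k0 = (int)std::floor(fz);
    if (i0 < 0) i0 = 0; if (i0 > nx - 2) i0 = nx - 2;
    if (j0 < 0) j0 = 0; if (j0 > ny - 2) j0 = ny - 2;
    if (k0 < 0) k0 = 0; if (k0 > nz - 2) k0 = nz - 2;
    double tx = fx - i0, ty = fy - j0, tz = fz - k0;
    if (tx < 0) tx = 0; if (tx > 1) tx = 1;
    if (ty < 0) ty = 0; if (ty > 1) ty = 1;
    if (tz < 0) tz = 0; if (tz > 1) tz = 1;
    double acc = 0;
    for (int dz2 = 0; dz2 < 2; ++dz2)
      for (int dy2 = 0; dy2 < 2; ++dy2)
        for (int dx2 = 0; dx2 < 2; ++dx2) {
          double w = (dx2 ? tx : 1 - tx) * (dy2 ? ty : 1 - ty) * (dz2 ? tz : 1 - tz);
          acc += w * field[corner_index(i0 + dx2, j0 + dy2, k0 + dz2)];
        }
    return acc;
  };

  for (R_xlen_t t = 0; t < ntri; ++t) {
    int a = t0[t], b = t1[t], c = t2[t];
    double cx = (vx[a] + vx[b] + vx[c]) / 3.0;
    double cy = (vy[a] + vy[b] + vy[c]) / 3.0;
    double cz = (vz[a] + vz[b] + vz[c]) / 3.0;
    double nxv = (vy[b] - vy[a]) * (vz[c] - vz[a]) - (vz[b] - vz[a]) * (vy[c] - vy[a]);
    double nyv = (vz[b] - vz[a]) * (vx[c] - vx[a]) - (vx[b] - vx[a]) * (vz[c] - vz[a]);
    double nzv = (vx[b] - vx[a]) * (vy[c] - vy[a]) - (vy[b] - vy[a]) * (vx[c] - vx[a]);
    double eps = 0.5 * spacing[0];
    double gx2 = field_at(cx + eps, cy, cz) - field_at(cx - eps, cy, cz);
    double gy2 = field_at(cx, cy + eps, cz) - field_at(cx, cy - eps, cz);
    double gz2 = field_at(cx, cy, cz + eps) - field_at(cx, cy, cz - eps);
    if (nxv * gx2 + nyv * gy2 + nzv * gz2 < 0) std::swap(t1[t], t2[t]);
  }

  R_xlen_t nv = vx.size();
  NumericMatrix V(nv, 3);
  for (R_xlen_t i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix T(ntri, 3);
  for (R_xlen_t t = 0; t < ntri; ++t) {
    T(t, 0) = t0[t] + 1; T(t, 1) = t1[t] + 1; T(t, 2) = t2[t] + 1;
  }
  return List::create(_["vertices"] = V, _["triangles"] = T);
}
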