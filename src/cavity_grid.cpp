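// Occupancy-grid kernels for interior-cavity detection: sphere stamping
// and 6-connected flood-fill labelling of free space.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Mark voxels whose centre lies within radii[i] of atom i.
// grid voxel (ix,iy,iz) centre = origin + (ix,iy,iz)*spacing, 0-based.
// [[Rcpp::export]]
LogicalVector cpp_occupancy(IntegerVector dim, NumericVector origin,
                            double spacing, NumericMatrix coords,
                            NumericVector radii) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector occ(static_cast<R_xlen_t>(nx) * ny * nz, false);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    const double r = radii[a], r2 = r * r;
    int ix0 = std::max(0, (int)std::floor((cx - r - origin[0]) / spacing));
    int ix1 = std::min(nx - 1, (int)std::ceil((cx + r - origin[0]) / spacing));
    int iy0 = std::max(0, (int)std::floor((cy - r - origin[1]) / spacing));
    int iy1 = std::min(ny - 1, (int)std::ceil((cy + r - origin[1]) / spacing));
    int iz0 = std::max(0, (int)std::floor((cz - r - origin[2]) / spacing));
    int iz1 = std::min(nz - 1, (int)std::ceil((cz + r - origin[2]) / spacing));
    for (int iz = iz0; iz <= iz1; ++iz) {
      const double dz = origin[2] + iz * spacing - cz;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = origin[1] + iy * spacing - cy;
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int ix = ix0; ix <= ix1; ++ix) {
          const double dx = origin[0] + ix * spacing - cx;
          if (dx * dx + dyz <= r2) {
            occ[(R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix] = true;
          }
        }
      }
    }
  }
  occ.attr("dim") = dim;
  return occ;
}

// Label free voxels by 6-connected component: 0 = occupied, 1 = exterior
// (connected to any grid boundary), 2.. = interior components (cavities),
// in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_label_free(LogicalVector occ, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  IntegerVector lab(n, NA_INTEGER);
  for (R_xlen_t i = 0; i < n; ++i) if (occ[i]) lab[i] = 0;

  std::queue<R_xlen_t> q;
  auto idx = [&](int ix, int iy, int iz) {
    return (R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx + ix;
  };
  auto flood = [&](R_xlen_t seed, int label) {
    lab[seed] = label;
    q.push(seed);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int ix = (int)(cur % nx);
      int iy = (int)((cur / nx) % ny);
      int iz = (int)(cur / ((R_xlen_t)nx * ny));
      const int dx[6] = {1, -1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, 1, -1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, 1, -1};
      for (int k = 0; k < 6; ++k) {
        int jx = ix + dx[k], jy = iy + dy[k], jz = iz + dz[k];
        if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
          continue;
        R_xlen_t j = idx(jx, jy, jz);
        if (lab[j] == NA_INTEGER) {
          lab[j] = label;
          q.push(j);
        }
      }
    }
  };

  // exterior: everything reachable from free boundary voxels
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        bool boundary = ix == 0 || ix == nx - 1 || iy == 0 || iy == ny - 1 ||
                        iz == 0 || iz == nz - 1;
        if (!boundary) continue;
        R_xlen_t i = idx(ix, iy, iz);
        if (lab[i] == NA_INTEGER) flood(i, 1);
      }

  // remaining free voxels: interior components
  int next_label = 2;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] == NA_INTEGER) flood(i, next_label++);
  }
  lab.attr("dim") = dim;
  return lab;
}
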