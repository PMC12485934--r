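// Voxel-lattice primitives behind the cavity-geometry module.
// Grids are logical R arrays in column-major order; voxel (i,j,k) (0-based)
// has linear index i + j*nx + k*nx*ny and center origin + (i+0.5)*voxel.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
LogicalVector stamp_spheres_cpp(NumericMatrix coords, double radius,
                                NumericVector origin, double voxel,
                                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const double r2 = radius * radius;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double cx = coords(a, 0), cy = coords(a, 1), cz = coords(a, 2);
    int ilo = (int)std::ceil((cx - radius - origin[0]) / voxel - 0.5);
    int ihi = (int)std::floor((cx + radius - origin[0]) / voxel - 0.5);
    int jlo = (int)std::ceil((cy - radius - origin[1]) / voxel - 0.5);
    int jhi = (int)std::floor((cy + radius - origin[1]) / voxel - 0.5);
    int klo = (int)std::ceil((cz - radius - origin[2]) / voxel - 0.5);
    int khi = (int)std::floor((cz + radius - origin[2]) / voxel - 0.5);
    if (ilo < 0) ilo = 0; if (jlo < 0) jlo = 0; if (klo < 0) klo = 0;
    if (ihi >= nx) ihi = nx - 1; if (jhi >= ny) jhi = ny - 1; if (khi >= nz) khi = nz - 1;
    for (int k = klo; k <= khi; ++k) {
      const double dz = origin[2] + (k + 0.5) * voxel - cz;
      for (int j = jlo; j <= jhi; ++j) {
        const double dy = origin[1] + (j + 0.5) * voxel - cy;
        const double dyz = dy * dy + dz * dz;
        if (dyz > r2) continue;
        for (int i = ilo; i <= ihi; ++i) {
          const double dx = origin[0] + (i + 0.5) * voxel - cx;
          if (dx * dx + dyz <= r2) out[idx3(i, j, k, nx, ny)] = true;
        }
      }
    }
  }
  return out;
}

// empty (non-blocked) voxels reachable from the grid boundary, 6-connected
// [[Rcpp::export]]
LogicalVector flood_exterior_cpp(LogicalVector blocked, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector reach(n);
  std::vector<int> stack;
  stack.reserve(1 << 16);
  // seed every boundary face voxel that is empty
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 && k != nz - 1)
          continue;
        int id = idx3(i, j, k, nx, ny);
        if (!blocked[id] && !reach[id]) { reach[id] = true; stack.push_back(id); }
      }
  const int nxy = nx * ny;
  while (!stack.empty()) {
    int id = stack.back(); stack.pop_back();
    int k = id / nxy, rem = id % nxy, j = rem / nx, i = rem % nx;
    const int di[6] = {1, -1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, 1, -1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, 1, -1};
    for (int t = 0; t < 6; ++t) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      int nid = idx3(ii, jj, kk, nx, ny);
      if (!blocked[nid] && !reach[nid]) { reach[nid] = true; stack.push_back(nid); }
    }
  }
  return reach;
}

// Euclidean dilation of a mask by `radius` voxels: only boundary voxels of
// the mask are stamped, which keeps the cost proportional to surface area.
// [[Rcpp::export]]
LogicalVector dilate_mask_cpp(LogicalVector mask, IntegerVector dims,
                              double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out = clone(mask);
  const int r = (int)std::floor(radius);
  const double r2 = radius * radius;
  const int di[6] = {1, -1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, 1, -1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, 1, -1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = idx3(i, j, k, nx, ny);
        if (!mask[id]) continue;
        bool boundary = (i == 0 || i == nx - 1 || j == 0 || j == ny - 1 ||
                         k == 0 || k == nz - 1);
        for (int t = 0; t < 6 && !boundary; ++t) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (!mask[idx3(ii, jj, kk, nx, ny)]) boundary = true;
        }
        if (!boundary) continue;
        for (int dk2 = -r; dk2 <= r; ++dk2) {
          int kk = k + dk2; if (kk < 0 || kk >= nz) continue;
          for (int dj2 = -r; dj2 <= r; ++dj2) {
            int jj = j + dj2; if (jj < 0 || jj >= ny) continue;
            const int dd = dk2 * dk2 + dj2 * dj2;
            if (dd > r2) continue;
            for (int di2 = -r; di2 <= r; ++di2) {
              int ii = i + di2; if (ii < 0 || ii >= nx) continue;
              if (di2 * di2 + dd <= r2) out[idx3(ii, jj, kk, nx, ny)] = true;
            }
          }
        }
      }
  return out;
}

// connected-component labels (1..K, in first-voxel order) of a mask
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> stack;
  int next = 0;
  const int nxy = nx * ny;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      int k = id / nxy, rem = id % nxy, j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (man == 0) continue;
            if (connectivity == 6 && man != 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            int nid = idx3(ii, jj, kk, nx, ny);
            if (mask[nid] && !lab[nid]) { lab[nid] = next; stack.push_back(nid); }
          }
    }
  }
  return lab;
}

// nearest-mask classification of points: 1 interior, 2 exterior, 3 buried
// [[Rcpp::export]]
IntegerVector classify_points_cpp(NumericMatrix points, LogicalVector cavity,
                                  LogicalVector exterior, IntegerVector dims,
                                  NumericVector origin, double voxel,
                                  double reach, double tie) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(points.nrow());
  for (int p = 0; p < points.nrow(); ++p) {
    const double px = points(p, 0), py = points(p, 1), pz = points(p, 2);
    int ilo = (int)std::ceil((px - reach - origin[0]) / voxel - 0.5);
    int ihi = (int)std::floor((px + reach - origin[0]) / voxel - 0.5);
    int jlo = (int)std::ceil((py - reach - origin[1]) / voxel - 0.5);
    int jhi = (int)std::floor((py + reach - origin[1]) / voxel - 0.5);
    int klo = (int)std::ceil((pz - reach - origin[2]) / voxel - 0.5);
    int khi = (int)std::floor((pz + reach - origin[2]) / voxel - 0.5);
    if (ilo < 0) ilo = 0; if (jlo < 0) jlo = 0; if (klo < 0) klo = 0;
    if (ihi >= nx) ihi = nx - 1; if (jhi >= ny) jhi = ny - 1; if (khi >= nz) khi = nz - 1;
    double dcav = R_PosInf, dext = R_PosInf;
    const double reach2 = reach * reach;
    for (int k = klo; k <= khi; ++k) {
      const double dz = origin[2] + (k + 0.5) * voxel - pz;
      for (int j = jlo; j <= jhi; ++j) {
        const double dy = origin[1] + (j + 0.5) * voxel - py;
        const double dyz = dy * dy + dz * dz;
        if (dyz > reach2) continue;
        for (int i = ilo; i <= ihi; ++i) {
          const double dx = origin[0] + (i + 0.5) * voxel - px;
          const double d2 = dx * dx + dyz;
          if (d2 > reach2) continue;
          int id = idx3(i, j, k, nx, ny);
          if (cavity[id] && d2 < dcav) dcav = d2;
          if (exterior[id] && d2 < dext) dext = d2;
        }
      }
    }
    dcav = std::sqrt(dcav); dext = std::sqrt(dext);
    if (!R_FINITE(dcav) && !R_FINITE(dext)) out[p] = 3;
    else if (R_FINITE(dcav) && R_FINITE(dext) && std::abs(dcav - dext) <= tie) out[p] = 3;
    else if (dcav < dext) out[p] = 1;
    else out[p] = 2;
  }
  return out;
}
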