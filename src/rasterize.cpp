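// Voxelization of axis-aligned ellipsoids/balls into an integer label array.
// A voxel belongs to an object when its CENTRE lies inside the analytic
// surface; voxel (i,j,k) (0-based) has centre ((i+.5)dy, (j+.5)dx, (k+.5)dz).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// jobs: columns (cy, cx, cz, ry, rx, rz, label) in um / label id.
// only_empty: claim only unassigned voxels (first-come ownership).
// [[Rcpp::export]]
IntegerVector cpp_stamp(IntegerVector arr, int ny, int nx, int nz,
                        NumericVector spacing, NumericMatrix jobs,
                        bool only_empty) {
  const double dy = spacing[0], dx = spacing[1], dz = spacing[2];
  for (int r = 0; r < jobs.nrow(); ++r) {
    const double cy = jobs(r, 0), cx = jobs(r, 1), cz = jobs(r, 2);
    const double ry = jobs(r, 3), rx = jobs(r, 4), rz = jobs(r, 5);
    const int lab = (int)jobs(r, 6);
    const int y0 = std::max(0, (int)std::floor((cy - ry) / dy - 0.5));
    const int y1 = std::min(ny - 1, (int)std::ceil((cy + ry) / dy - 0.5));
    const int x0 = std::max(0, (int)std::floor((cx - rx) / dx - 0.5));
    const int x1 = std::min(nx - 1, (int)std::ceil((cx + rx) / dx - 0.5));
    const int z0 = std::max(0, (int)std::floor((cz - rz) / dz - 0.5));
    const int z1 = std::min(nz - 1, (int)std::ceil((cz + rz) / dz - 0.5));
    for (int k = z0; k <= z1; ++k) {
      const double fz = ((k + 0.5) * dz - cz) / rz;
      for (int j = x0; j <= x1; ++j) {
        const double fx = ((j + 0.5) * dx - cx) / rx;
        for (int i = y0; i <= y1; ++i) {
          const double fy = ((i + 0.5) * dy - cy) / ry;
          if (fy * fy + fx * fx + fz * fz <= 1.0) {
            R_xlen_t idx = i + (R_xlen_t)ny * (j + (R_xlen_t)nx * k);
            if (!only_empty || arr[idx] == 0) arr[idx] = lab;
          }
        }
      }
    }
  }
  return arr;
}
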