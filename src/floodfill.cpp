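// Grid flood-fill oracle for void counting and volume cross-checks.
// Test-only ground truth, independent of the Voronoi complement pipeline:
// rasterize probe accessibility (distance to every atom center exceeds
// r_i + delta, compared squared with early exit), flood the exterior from
// the box boundary (26-connectivity), label the remaining accessible cells
// into connected components (voids).

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline R_xlen_t at(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
}

// [[Rcpp::export]]
List flood_voids_cpp(NumericMatrix centers, NumericVector radii,
                     NumericVector origin, IntegerVector dims, double step,
                     double delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int na = centers.nrow();
  std::vector<double> cx(na), cy(na), cz(na), rr2(na);
  for (int a = 0; a < na; ++a) {
    cx[a] = centers(a, 0); cy[a] = centers(a, 1); cz[a] = centers(a, 2);
    double r = radii[a] + delta;
    rr2[a] = r * r;
  }
  // -1 unvisited accessible, 0 blocked
  std::vector<int> lab(n);
  {
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      double z = origin[2] + k * step;
      for (int j = 0; j < ny; ++j) {
        double y = origin[1] + j * step;
        for (int i = 0; i < nx; ++i, ++idx) {
          double x = origin[0] + i * step;
          int l = -1;
          for (int a = 0; a < na; ++a) {
            double dx = x - cx[a], dy = y - cy[a], dz = z - cz[a];
            if (dx * dx + dy * dy + dz * dz <= rr2[a]) { l = 0; break; }
          }
          lab[idx] = l;
        }
      }
    }
  }
  std::queue<R_xlen_t> bfs;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        R_xlen_t q = at(i, j, k, nx, ny);
        if (lab[q] == -1) { lab[q] = 1; bfs.push(q); }
      }
  int next_label = 1;
  std::vector<double> sizes;
  while (true) {
    while (!bfs.empty()) {
      R_xlen_t q = bfs.front(); bfs.pop();
      int k = (int)(q / ((R_xlen_t)nx * ny));
      int rem = (int)(q % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      int cur = lab[q];
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny ||
                kk >= nz) continue;
            R_xlen_t p = at(ii, jj, kk, nx, ny);
            if (lab[p] == -1) {
              lab[p] = cur;
              if (cur > 1) sizes[cur - 2] += 1.0;
              bfs.push(p);
            }
          }
    }
    R_xlen_t seed = -1;
    for (R_xlen_t q = 0; q < n; ++q) if (lab[q] == -1) { seed = q; break; }
    if (seed < 0) break;
    ++next_label;
    lab[seed] = next_label;
    sizes.push_back(1.0);
    bfs.push(seed);
  }
  return List::create(_["n_voids"] = next_label - 1,
                      _["void_voxels"] = NumericVector(sizes.begin(),
                                                       sizes.end()),
                      _["voxel_volume"] = step * step * step);
}
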