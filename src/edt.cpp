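#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform.
// f: input squared distances, d: output, n: length, w2: squared grid spacing.
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w2 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// Exact 3D Euclidean distance (in physical units) from every TRUE voxel of
// `mask` to the nearest FALSE voxel; FALSE voxels get distance 0.
// `spacing` gives the voxel pitch along each of the three axes.
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  // init: 0 at background, INF inside
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // pass along x (fastest-varying index)
  double w2 = spacing[0] * spacing[0];
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, nx, w2);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  // pass along y
  w2 = spacing[1] * spacing[1];
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, w2);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  w2 = spacing[2] * spacing[2];
  R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * nxy];
      dt1d(f, d, nz, w2);
      for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * nxy] = std::sqrt(d[z]);
    }
  return out;
}
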