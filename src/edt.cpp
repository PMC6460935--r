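// Exact 3D Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope algorithm, applied separably along each axis).
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform of sampled function f
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = -1;  // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; if (k < 0) break; } else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    double dq = q - v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
}

// Squared Euclidean distance (in voxel units) from every grid cell to the
// nearest seed cell. seeds: logical array of length nx*ny*nz (column-major).
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector seeds, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nfull = (size_t)nx * ny * nz;
  if ((size_t)seeds.size() != nfull) stop("seed mask does not match dims");
  std::vector<double> g(nfull);
  for (size_t i = 0; i < nfull; ++i) g[i] = seeds[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)j * nx + (size_t)k * nx * ny;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)k * nx * ny;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)i + (size_t)j * nx;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * nx * ny];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * nx * ny] = d[k];
    }
  return wrap(g);
}
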