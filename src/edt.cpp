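// Exact Euclidean distance transform (squared), separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher).  Input mask dim (nz, ny, nx);
// output: for each foreground voxel, squared distance (voxel units) to the
// nearest background voxel centre; 0 on background.  A volume with no
// background returns a large finite sentinel.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D squared distance transform of sampled function f, result into d.
static void dt1d(const double* f, double* d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t ntot = (size_t)nz * ny * nx;
  NumericVector out(ntot);
  double* g = out.begin();
  for (size_t i = 0; i < ntot; ++i) g[i] = mask[i] ? DT_INF : 0.0;

  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double* col = g + (size_t)nz * (y + (size_t)ny * x);
      dt1d(col, f.data(), nz, v, z);
      for (int i = 0; i < nz; ++i) col[i] = f[i];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      double* base = g + zz + (size_t)nz * (size_t)ny * x;
      for (int y = 0; y < ny; ++y) f[y] = base[(size_t)nz * y];
      dt1d(f.data(), d.data(), ny, v, z);
      for (int y = 0; y < ny; ++y) base[(size_t)nz * y] = d[y];
    }
  // pass along x (stride nz*ny)
  const size_t sx = (size_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      double* base = g + zz + (size_t)nz * y;
      for (int x = 0; x < nx; ++x) f[x] = base[sx * x];
      dt1d(f.data(), d.data(), nx, v, z);
      for (int x = 0; x < nx; ++x) base[sx * x] = d[x];
    }

  out.attr("dim") = dims;
  return out;
}
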