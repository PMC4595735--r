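// Parallel-beam forward projection and back-projection kernels.
//
// Volumes are R arrays with dim = c(nz, ny, nx); linear index
// z + nz * (y + ny * x).  The rotation axis is the vertical (z) axis,
// so every z-slice undergoes the same in-plane transform.  In-plane
// coordinates: x = column axis, y = row axis, both centred at
// c = (n - 1) / 2.  For angle theta the beam direction is
// d = (cos t, sin t) in (x, y) and the detector axis is
// e = (-sin t, cos t); the line integral at detector coordinate u is
// p(u) = sum_t f(c + u e + t d), sampled at unit-voxel steps with
// bilinear interpolation.  The (u, t) grid is symmetric about the
// centre, which makes p_{theta+pi}(u) the exact mirror of p_theta(u).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_project(NumericVector vol, IntegerVector dims,
                          NumericVector angles) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  if (ny != nx) stop("in-plane volume section must be square");
  const int n = nx;
  const int na = angles.size();
  const double c = (n - 1) / 2.0;
  // symmetric integration range covering the slice diagonal
  const int tmax = (int)std::ceil(n * 0.70710678118654752 + 1.0);

  NumericVector out(na * nz * n);  // dim (na, nz, n)
  const double* v = vol.begin();
  double* o = out.begin();

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int ui = 0; ui < n; ++ui) {
      const double u = ui - c;
      for (int t = -tmax; t <= tmax; ++t) {
        const double x = c - u * st + t * ct;
        const double y = c + u * ct + t * st;
        if (x < 0 || x > n - 1 || y < 0 || y > n - 1) continue;
        int ix = (int)std::floor(x), iy = (int)std::floor(y);
        if (ix == n - 1) ix--;
        if (iy == n - 1) iy--;
        const double fx = x - ix, fy = y - iy;
        const double w00 = (1 - fx) * (1 - fy), w01 = (1 - fx) * fy;
        const double w10 = fx * (1 - fy), w11 = fx * fy;
        const double* col00 = v + (size_t)nz * (iy + (size_t)ny * ix);
        const double* col01 = col00 + nz;                // y + 1
        const double* col10 = col00 + (size_t)nz * ny;   // x + 1
        const double* col11 = col10 + nz;
        double* oc = o + a + (size_t)na * (size_t)nz * ui;
        for (int z = 0; z < nz; ++z)
          oc[(size_t)na * z] += w00 * col00[z] + w01 * col01[z] +
                                w10 * col10[z] + w11 * col11[z];
      }
    }
  }
  out.attr("dim") = IntegerVector::create(na, nz, n);
  return out;
}

// Back-projection of a stack of filtered sinograms.
// filt has dim (na, nz, nu); returns (nz, n, n) with n = nu.
// Accumulates interp_u filt[a, z, u(x, y)] per pixel; the caller applies
// the pi / na normalisation.
// [[Rcpp::export]]
NumericVector cpp_backproject_stack(NumericVector filt, IntegerVector dims,
                                    NumericVector angles) {
  const int na = dims[0], nz = dims[1], nu = dims[2];
  const int n = nu;
  const double c = (n - 1) / 2.0;
  NumericVector out((size_t)nz * n * n);  // dim (nz, n, n)
  const double* f = filt.begin();
  double* o = out.begin();

  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int x = 0; x < n; ++x) {
      const double ex = -(x - c) * st;
      for (int y = 0; y < n; ++y) {
        const double u = ex + (y - c) * ct + c;
        if (u < 0 || u > nu - 1) continue;
        int iu = (int)std::floor(u);
        if (iu == nu - 1) iu--;
        const double fu = u - iu;
        const double* f0 = f + a + (size_t)na * (size_t)nz * iu;
        const double* f1 = f0 + (size_t)na * nz;
        double* oc = o + (size_t)nz * (y + (size_t)n * x);
        for (int z = 0; z < nz; ++z) {
          const size_t zz = (size_t)na * z;
          oc[z] += (1 - fu) * f0[zz] + fu * f1[zz];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, n, n);
  return out;
}
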