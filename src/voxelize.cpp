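// Rasterisation of a branching-tube vessel tree into a binary voxel mask.
// A voxel (centre p) is vessel iff for some edge and some t in [0, 1]
// |p - c(t)| <= r(t), with c linear between the edge's endpoints and r
// linearly interpolated (tapered tube).  For constant radius this is the
// exact capsule test; for tapered edges g(t) = |p - c(t)| - r(t) is convex
// in t and is minimised by golden-section search.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double seg_g(double t, const double* a, const double* b,
                           double ra, double rb, const double* p) {
  const double cx = a[0] + t * (b[0] - a[0]);
  const double cy = a[1] + t * (b[1] - a[1]);
  const double cz = a[2] + t * (b[2] - a[2]);
  const double dx = p[0] - cx, dy = p[1] - cy, dz = p[2] - cz;
  return std::sqrt(dx * dx + dy * dy + dz * dz) - (ra + t * (rb - ra));
}

// positions and radii in voxel units (0-based voxel-centre coordinates,
// columns x, y, z); dims = (nz, ny, nx).
// [[Rcpp::export]]
List cpp_voxelize(NumericMatrix pos, NumericVector radius,
                  IntegerMatrix edges, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  IntegerVector mask((size_t)nz * ny * nx);
  int* m = mask.begin();
  bool clipped = false;
  const double eps = 1e-9;

  for (int e = 0; e < edges.nrow(); ++e) {
    const int ia = edges(e, 0), ib = edges(e, 1);
    double a[3] = { pos(ia, 0), pos(ia, 1), pos(ia, 2) };
    double b[3] = { pos(ib, 0), pos(ib, 1), pos(ib, 2) };
    const double ra = radius[ia], rb = radius[ib];
    const double rmax = std::max(ra, rb);
    const int x0 = std::max(0, (int)std::floor(std::min(a[0], b[0]) - rmax - 1));
    const int x1 = std::min(nx - 1, (int)std::ceil(std::max(a[0], b[0]) + rmax + 1));
    const int y0 = std::max(0, (int)std::floor(std::min(a[1], b[1]) - rmax - 1));
    const int y1 = std::min(ny - 1, (int)std::ceil(std::max(a[1], b[1]) + rmax + 1));
    const int z0 = std::max(0, (int)std::floor(std::min(a[2], b[2]) - rmax - 1));
    const int z1 = std::min(nz - 1, (int)std::ceil(std::max(a[2], b[2]) + rmax + 1));
    if (std::min(a[0], b[0]) - rmax < -0.5 || std::max(a[0], b[0]) + rmax > nx - 0.5 ||
        std::min(a[1], b[1]) - rmax < -0.5 || std::max(a[1], b[1]) + rmax > ny - 0.5 ||
        std::min(a[2], b[2]) - rmax < -0.5 || std::max(a[2], b[2]) + rmax > nz - 0.5)
      clipped = true;

    const double vx = b[0] - a[0], vy = b[1] - a[1], vz = b[2] - a[2];
    const double vv = vx * vx + vy * vy + vz * vz;
    const bool constant_r = std::fabs(ra - rb) < 1e-12;

    for (int x = x0; x <= x1; ++x)
      for (int y = y0; y <= y1; ++y)
        for (int z = z0; z <= z1; ++z) {
          const size_t s = z + (size_t)nz * (y + (size_t)ny * x);
          if (m[s]) continue;
          const double p[3] = { (double)x, (double)y, (double)z };
          bool in;
          if (constant_r || vv < 1e-24) {
            // exact point-to-segment distance
            double t = 0.0;
            if (vv >= 1e-24) {
              t = ((p[0] - a[0]) * vx + (p[1] - a[1]) * vy +
                   (p[2] - a[2]) * vz) / vv;
              t = std::min(1.0, std::max(0.0, t));
            }
            in = seg_g(t, a, b, ra, rb, p) <= eps;
          } else {
            // golden-section minimisation of the convex g(t)
            const double gr = 0.61803398874989485;
            double lo = 0.0, hi = 1.0;
            double t1 = hi - gr * (hi - lo), t2 = lo + gr * (hi - lo);
            double g1 = seg_g(t1, a, b, ra, rb, p);
            double g2 = seg_g(t2, a, b, ra, rb, p);
            for (int it = 0; it < 60; ++it) {
              if (g1 <= g2) { hi = t2; t2 = t1; g2 = g1;
                t1 = hi - gr * (hi - lo); g1 = seg_g(t1, a, b, ra, rb, p); }
              else { lo = t1; t1 = t2; g1 = g2;
                t2 = lo + gr * (hi - lo); g2 = seg_g(t2, a, b, ra, rb, p); }
            }
            const double gmin = std::min(
              std::min(g1, g2),
              std::min(seg_g(0.0, a, b, ra, rb, p),
                       seg_g(1.0, a, b, ra, rb, p)));
            in = gmin <= eps;
          }
          if (in) m[s] = 1;
        }
  }
  mask.attr("dim") = dims;
  return List::create(_["mask"] = mask, _["clipped"] = clipped);
}
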