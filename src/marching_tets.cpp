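// Iso-surface extraction by the tetrahedral decomposition of the marching
// cubes grid.  Each cell between 8 voxel centres is split into 6 tetrahedra
// around the main diagonal; the split is translation-invariant, so shared
// faces of neighbouring cells carry the same diagonal and the resulting
// surface is watertight.  Vertices are created on tetrahedron edges by
// linear interpolation to the iso level and de-duplicated via a quantised
// coordinate map, so meshes are usable directly for Euler-characteristic
// and enclosed-volume computations.
//
// field has dim (nz, ny, nx); output vertex coordinates are (x, y, z) in
// voxel-index units.  Triangles are wound so normals point away from the
// interior (field > iso) side.
#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct VKey {
  int64_t x, y, z;
  bool operator<(const VKey& o) const {
    if (x != o.x) return x < o.x;
    if (y != o.y) return y < o.y;
    return z < o.z;
  }
};

// cube corner offsets (x, y, z)
static const int corner[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// six tetrahedra around main diagonal 0-6
static const int tets[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector field, IntegerVector dims, double iso) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double* f = field.begin();
  std::map<VKey, int> vmap;
  std::vector<double> verts;       // x,y,z triples
  std::vector<int> faces;          // 0-based triples

  auto val = [&](int x, int y, int z) -> double {
    return f[z + (size_t)nz * (y + (size_t)ny * x)];
  };
  auto add_vert = [&](double x, double y, double z) -> int {
    VKey k{ (int64_t)llround(x * 1048576.0), (int64_t)llround(y * 1048576.0),
            (int64_t)llround(z * 1048576.0) };
    auto it = vmap.find(k);
    if (it != vmap.end()) return it->second;
    const int id = (int)(verts.size() / 3);
    verts.push_back(x); verts.push_back(y); verts.push_back(z);
    vmap[k] = id;
    return id;
  };

  double P[8][3], V[8];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          P[c][0] = x + corner[c][0];
          P[c][1] = y + corner[c][1];
          P[c][2] = z + corner[c][2];
          V[c] = val(x + corner[c][0], y + corner[c][1], z + corner[c][2]);
          (V[c] > iso ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int inside[4], nin = 0;
          for (int c = 0; c < 4; ++c)
            if (V[tv[c]] > iso) inside[nin++] = c;
          if (nin == 0 || nin == 4) continue;

          // interpolated vertex on edge (a, b) of the tetrahedron
          auto edge_vert = [&](int a, int b) -> int {
            const int ia = tv[a], ib = tv[b];
            const double t01 = (iso - V[ia]) / (V[ib] - V[ia]);
            return add_vert(P[ia][0] + t01 * (P[ib][0] - P[ia][0]),
                            P[ia][1] + t01 * (P[ib][1] - P[ia][1]),
                            P[ia][2] + t01 * (P[ib][2] - P[ia][2]));
          };
          auto emit = [&](int a, int b, int c, int in_corner) {
            // orient so the normal points away from the inside corner
            const double* q = P[tv[in_corner]];
            const double* va = &verts[3 * a];
            const double* vb = &verts[3 * b];
            const double* vc = &verts[3 * c];
            const double ux = vb[0] - va[0], uy = vb[1] - va[1],
                         uz = vb[2] - va[2];
            const double wx = vc[0] - va[0], wy = vc[1] - va[1],
                         wz = vc[2] - va[2];
            const double nxv = uy * wz - uz * wy;
            const double nyv = uz * wx - ux * wz;
            const double nzv = ux * wy - uy * wx;
            const double dot = nxv * (va[0] - q[0]) + nyv * (va[1] - q[1]) +
                               nzv * (va[2] - q[2]);
            if (dot >= 0) { faces.push_back(a); faces.push_back(b); faces.push_back(c); }
            else          { faces.push_back(a); faces.push_back(c); faces.push_back(b); }
          };

          if (nin == 1 || nin == 3) {
            // one corner separated: single triangle
            int lone = -1;
            if (nin == 1) lone = inside[0];
            else {
              for (int c = 0; c < 4; ++c) {
                bool found = false;
                for (int k = 0; k < nin; ++k) if (inside[k] == c) found = true;
                if (!found) { lone = c; break; }
              }
            }
            int others[3], no = 0;
            for (int c = 0; c < 4; ++c) if (c != lone) others[no++] = c;
            const int v0 = edge_vert(lone, others[0]);
            const int v1 = edge_vert(lone, others[1]);
            const int v2 = edge_vert(lone, others[2]);
            emit(v0, v1, v2, nin == 1 ? lone : others[0]);
          } else {
            // two in, two out: quad split into two triangles
            int in0 = inside[0], in1 = inside[1];
            int out[2], no = 0;
            for (int c = 0; c < 4; ++c)
              if (c != in0 && c != in1) out[no++] = c;
            const int v00 = edge_vert(in0, out[0]);
            const int v01 = edge_vert(in0, out[1]);
            const int v10 = edge_vert(in1, out[0]);
            const int v11 = edge_vert(in1, out[1]);
            emit(v00, v10, v11, in0);
            emit(v00, v11, v01, in0);
          }
        }
      }

  const int nv = (int)(verts.size() / 3);
  NumericMatrix vm(nv, 3);
  for (int i = 0; i < nv; ++i) {
    vm(i, 0) = verts[3 * i];
    vm(i, 1) = verts[3 * i + 1];
    vm(i, 2) = verts[3 * i + 2];
  }
  const int nf = (int)(faces.size() / 3);
  IntegerMatrix fm(nf, 3);
  for (int i = 0; i < nf; ++i) {
    fm(i, 0) = faces[3 * i];
    fm(i, 1) = faces[3 * i + 1];
    fm(i, 2) = faces[3 * i + 2];
  }
  return List::create(_["vertices"] = vm, _["faces"] = fm);
}
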