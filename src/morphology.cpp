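// 3D connected-component labelling (6- or 26-connectivity) and
// topology-preserving thinning to unit-width centerlines.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_label(IntegerVector mask, IntegerVector dims,
                        int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t ntot = (size_t)nz * ny * nx;
  IntegerVector lab(ntot);
  std::vector<int> dzv, dyv, dxv;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        dzv.push_back(dz); dyv.push_back(dy); dxv.push_back(dx);
      }
  const int nn = dzv.size();
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back(); stack.pop_back();
      const int z = cur % nz;
      const int y = (cur / nz) % ny;
      const int x = cur / ((size_t)nz * ny);
      for (int k = 0; k < nn; ++k) {
        const int z2 = z + dzv[k], y2 = y + dyv[k], x2 = x + dxv[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
          continue;
        const size_t q = z2 + (size_t)nz * (y2 + (size_t)ny * x2);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// ---- simple-point machinery ------------------------------------------------

// neighbourhood is a 27-element 0/1 array indexed dz+1 + 3*(dy+1) + 9*(dx+1)
// (centre at index 13).  A voxel is simple iff deleting it preserves both
// foreground and background topology: exactly one 26-component of foreground
// in the 26-neighbourhood, and exactly one 6-component of background in the
// 18-neighbourhood that is 6-adjacent to the centre.

static inline int nidx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

static int fg_components26(const int* nb) {
  int seen[27]; std::memset(seen, 0, sizeof(seen));
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp;
    int stack[27], top = 0;
    stack[top++] = i; seen[i] = 1;
    while (top) {
      const int cur = stack[--top];
      const int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            const int z2 = cz + dz, y2 = cy + dy, x2 = cx + dx;
            if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2)
              continue;
            const int j = z2 + 3 * (y2 + 3 * x2);
            if (j == 13 || j == cur || !nb[j] || seen[j]) continue;
            seen[j] = 1; stack[top++] = j;
          }
    }
  }
  return ncomp;
}

static int bg_components6(const int* nb) {
  // 6-components of background restricted to the 18-neighbourhood,
  // counting only components 6-adjacent to the centre.
  int seen[27]; std::memset(seen, 0, sizeof(seen));
  int ncomp = 0;
  static const int face[6] = { nidx(-1, 0, 0), nidx(1, 0, 0), nidx(0, -1, 0),
                               nidx(0, 1, 0),  nidx(0, 0, -1), nidx(0, 0, 1) };
  for (int s = 0; s < 6; ++s) {
    const int start = face[s];
    if (nb[start] || seen[start]) continue;
    ++ncomp;
    int stack[27], top = 0;
    stack[top++] = start; seen[start] = 1;
    while (top) {
      const int cur = stack[--top];
      const int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
      static const int d6[6][3] = { {1,0,0},{-1,0,0},{0,1,0},{0,-1,0},
                                    {0,0,1},{0,0,-1} };
      for (int k = 0; k < 6; ++k) {
        const int z2 = cz + d6[k][0], y2 = cy + d6[k][1], x2 = cx + d6[k][2];
        if (z2 < 0 || z2 > 2 || y2 < 0 || y2 > 2 || x2 < 0 || x2 > 2) continue;
        const int man = std::abs(z2 - 1) + std::abs(y2 - 1) + std::abs(x2 - 1);
        if (man > 2) continue;  // stay inside the 18-neighbourhood
        const int j = z2 + 3 * (y2 + 3 * x2);
        if (j == 13 || nb[j] || seen[j]) continue;
        seen[j] = 1; stack[top++] = j;
      }
    }
  }
  return ncomp;
}

struct Grid {
  const int* m; int nz, ny, nx;
  inline int at(int z, int y, int x) const {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return m[z + (size_t)nz * (y + (size_t)ny * x)];
  }
};

static void fill_nb(const Grid& g, int z, int y, int x, int* nb) {
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz)
        nb[nidx(dz, dy, dx)] = g.at(z + dz, y + dy, x + dx);
}

static inline bool is_simple(const int* nb) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

static inline int n26_count(const int* nb) {
  int c = 0;
  for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
  return c;
}

// Directional sequential thinning: per iteration, for each of the six face
// directions, simple non-endpoint border voxels are deleted one at a time
// (simplicity re-checked at deletion time, which guarantees topology
// preservation).  Endpoints (exactly one 26-neighbour) are retained so
// curve ends survive.
// [[Rcpp::export]]
IntegerVector cpp_thin(IntegerVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const size_t ntot = (size_t)nz * ny * nx;
  IntegerVector out(clone(mask));
  int* m = out.begin();
  Grid g{m, nz, ny, nx};
  static const int dirs[6][3] = { {-1,0,0},{1,0,0},{0,-1,0},
                                  {0,1,0},{0,0,-1},{0,0,1} };  // (dz,dy,dx)
  std::vector<size_t> cand;
  int nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t s = 0; s < ntot; ++s) {
        if (!m[s]) continue;
        const int z = s % nz;
        const int y = (s / nz) % ny;
        const int x = s / ((size_t)nz * ny);
        if (g.at(z + dirs[d][0], y + dirs[d][1], x + dirs[d][2])) continue;
        fill_nb(g, z, y, x, nb);
        const int nn = n26_count(nb);
        if (nn <= 1) continue;            // endpoint or isolated: keep
        if (is_simple(nb)) cand.push_back(s);
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        const size_t s = cand[k];
        const int z = s % nz;
        const int y = (s / nz) % ny;
        const int x = s / ((size_t)nz * ny);
        fill_nb(g, z, y, x, nb);
        const int nn = n26_count(nb);
        if (nn <= 1) continue;
        if (is_simple(nb)) { m[s] = 0; changed = true; }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
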