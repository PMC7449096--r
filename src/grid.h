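#ifndef NUTCT_GRID_H
#define NUTCT_GRID_H

#include <Rcpp.h>
#include <array>
#include <vector>
#include <cmath>

// Canonical grid layout shared by all kernels: dim(data) = c(nx, ny, nz),
// voxel (x, y, z) lives at linear index x + nx * (y + ny * z), i.e. the x
// axis is fastest in memory (R column-major storage of data[x, y, z]).

struct Grid {
  int nx, ny, nz;
  explicit Grid(const Rcpp::IntegerVector& d) : nx(d[0]), ny(d[1]), nz(d[2]) {}
  R_xlen_t n() const { return (R_xlen_t)nx * ny * nz; }
  R_xlen_t idx(int x, int y, int z) const {
    return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
  }
};

inline std::vector<std::array<int, 3> > neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3> > off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        std::array<int, 3> a = {{dx, dy, dz}};
        off.push_back(a);
      }
  return off;
}

#endif
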