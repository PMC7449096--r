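#include "grid.h"

using namespace Rcpp;

// ---- filters ---------------------------------------------------------------

// Separable Gaussian with replicated borders; sigma in voxel units.
// The 1-D kernel is normalised to unit sum, so a fully interior impulse
// conserves total intensity exactly.

static void conv_line(const std::vector<double>& w, int R, double* line,
                      std::vector<double>& tmp, int len, R_xlen_t stride) {
  for (int i = 0; i < len; ++i) {
    double acc = 0;
    for (int j = -R; j <= R; ++j) {
      int s = i + j;
      if (s < 0) s = 0;
      if (s >= len) s = len - 1;
      acc += w[j + R] * line[stride * s];
    }
    tmp[i] = acc;
  }
  for (int i = 0; i < len; ++i) line[stride * i] = tmp[i];
}

// Cache-aware separable passes: x lines are contiguous, y lines stay within
// one (x, y) plane, z lines are gathered into an (x, z) slab per y.
static void gauss_axis(std::vector<double>& vol, const Grid& g, int axis,
                       const std::vector<double>& w, int R) {
  int len = axis == 0 ? g.nx : (axis == 1 ? g.ny : g.nz);
  std::vector<double> tmp(len);
  if (axis == 0) {
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y)
        conv_line(w, R, &vol[g.idx(0, y, z)], tmp, len, 1);
  } else if (axis == 1) {
    for (int z = 0; z < g.nz; ++z) {
      double* plane = &vol[(R_xlen_t)g.nx * g.ny * z];
      for (int x = 0; x < g.nx; ++x)
        conv_line(w, R, plane + x, tmp, len, g.nx);
    }
  } else {
    std::vector<double> slab((R_xlen_t)g.nx * g.nz);
    for (int y = 0; y < g.ny; ++y) {
      for (int z = 0; z < g.nz; ++z) {
        const double* run = &vol[g.idx(0, y, z)];
        std::copy(run, run + g.nx, &slab[(R_xlen_t)g.nx * z]);
      }
      for (int x = 0; x < g.nx; ++x)
        conv_line(w, R, &slab[x], tmp, len, g.nx);
      for (int z = 0; z < g.nz; ++z)
        std::copy(&slab[(R_xlen_t)g.nx * z], &slab[(R_xlen_t)g.nx * (z + 1)],
                  &vol[g.idx(0, y, z)]);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dims,
                          double sigma) {
  Grid g(dims);
  NumericVector out = clone(vol);
  if (sigma <= 0) return out;
  int R = std::max(1, (int)std::ceil(3.5 * sigma));
  std::vector<double> w(2 * R + 1);
  double s = 0;
  for (int j = -R; j <= R; ++j) {
    w[j + R] = std::exp(-0.5 * j * j / (sigma * sigma));
    s += w[j + R];
  }
  for (size_t j = 0; j < w.size(); ++j) w[j] /= s;
  std::vector<double> buf(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) buf[i] = out[i];
  gauss_axis(buf, g, 0, w, R);
  gauss_axis(buf, g, 1, w, R);
  gauss_axis(buf, g, 2, w, R);
  for (R_xlen_t i = 0; i < g.n(); ++i) out[i] = buf[i];
  return out;
}

// Central-difference gradient magnitude (one-sided at borders), voxel units.

// [[Rcpp::export]]
NumericVector cpp_gradmag(NumericVector vol, IntegerVector dims) {
  Grid g(dims);
  NumericVector out(g.n());
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        int xm = std::max(0, x - 1), xp = std::min(g.nx - 1, x + 1);
        int ym = std::max(0, y - 1), yp = std::min(g.ny - 1, y + 1);
        int zm = std::max(0, z - 1), zp = std::min(g.nz - 1, z + 1);
        double gx = (vol[g.idx(xp, y, z)] - vol[g.idx(xm, y, z)]) / (xp - xm);
        double gy = (vol[g.idx(x, yp, z)] - vol[g.idx(x, ym, z)]) / (yp - ym);
        double gz = (vol[g.idx(x, y, zp)] - vol[g.idx(x, y, zm)]) / (zp - zm);
        out[g.idx(x, y, z)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return out;
}

// ---- surface area ----------------------------------------------------------
//
// Marching-tetrahedra isosurface area: each cell is split into the six
// tetrahedra around the (0,0,0)-(1,1,1) diagonal (one per axis-order
// permutation) and the level-set crossing inside each tetrahedron is
// triangulated by linear interpolation along its edges. Returns total area in
// voxel^2 units; the caller rescales by voxel_size^2.

static const int TETS[6][4] = {{0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
                               {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
static const int CORNER[8][3] = {{0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
                                 {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

static inline void interp_edge(const double* pa, const double* pb, double va,
                               double vb, double level, double* out) {
  double t = (level - va) / (vb - va);
  for (int k = 0; k < 3; ++k) out[k] = pa[k] + t * (pb[k] - pa[k]);
}

static inline double tri_area(const double* a, const double* b,
                              const double* c) {
  double u[3], v[3];
  for (int k = 0; k < 3; ++k) {
    u[k] = b[k] - a[k];
    v[k] = c[k] - a[k];
  }
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// [[Rcpp::export]]
double cpp_mt_area(NumericVector vol, IntegerVector dims, double level) {
  Grid g(dims);
  double total = 0;
  double v[8], p[8][3];
  for (int z = 0; z + 1 < g.nz; ++z)
    for (int y = 0; y + 1 < g.ny; ++y)
      for (int x = 0; x + 1 < g.nx; ++x) {
        bool above = false, below = false;
        for (int c = 0; c < 8; ++c) {
          v[c] = vol[g.idx(x + CORNER[c][0], y + CORNER[c][1],
                           z + CORNER[c][2])];
          if (v[c] >= level)
            above = true;
          else
            below = true;
          p[c][0] = x + CORNER[c][0];
          p[c][1] = y + CORNER[c][1];
          p[c][2] = z + CORNER[c][2];
        }
        if (!above || !below) continue;
        for (int t = 0; t < 6; ++t) {
          int in[4], out[4], ni = 0, no = 0;
          for (int c = 0; c < 4; ++c) {
            int ci = TETS[t][c];
            if (v[ci] >= level)
              in[ni++] = ci;
            else
              out[no++] = ci;
          }
          if (ni == 0 || ni == 4) continue;
          double q1[3], q2[3], q3[3], q4[3];
          if (ni == 1 || ni == 3) {
            int a = ni == 1 ? in[0] : out[0];
            int* oth = ni == 1 ? out : in;
            interp_edge(p[a], p[oth[0]], v[a], v[oth[0]], level, q1);
            interp_edge(p[a], p[oth[1]], v[a], v[oth[1]], level, q2);
            interp_edge(p[a], p[oth[2]], v[a], v[oth[2]], level, q3);
            total += tri_area(q1, q2, q3);
          } else {
            interp_edge(p[in[0]], p[out[0]], v[in[0]], v[out[0]], level, q1);
            interp_edge(p[in[0]], p[out[1]], v[in[0]], v[out[1]], level, q2);
            interp_edge(p[in[1]], p[out[1]], v[in[1]], v[out[1]], level, q3);
            interp_edge(p[in[1]], p[out[0]], v[in[1]], v[out[0]], level, q4);
            total += tri_area(q1, q2, q3) + tri_area(q1, q3, q4);
          }
        }
      }
  return total;
}

// Coarea surface estimate: integral of |grad| of a smoothed indicator equals
// the interface area. Used as the independent oracle route. Voxel^2 units.

// [[Rcpp::export]]
double cpp_coarea(NumericVector vol, IntegerVector dims) {
  Grid g(dims);
  double total = 0;
  for (int z = 1; z + 1 < g.nz; ++z)
    for (int y = 1; y + 1 < g.ny; ++y)
      for (int x = 1; x + 1 < g.nx; ++x) {
        double gx =
            0.5 * (vol[g.idx(x + 1, y, z)] - vol[g.idx(x - 1, y, z)]);
        double gy =
            0.5 * (vol[g.idx(x, y + 1, z)] - vol[g.idx(x, y - 1, z)]);
        double gz =
            0.5 * (vol[g.idx(x, y, z + 1)] - vol[g.idx(x, y, z - 1)]);
        total += std::sqrt(gx * gx + gy * gy + gz * gz);
      }
  return total;
}
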