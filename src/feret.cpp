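#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Caliper (Feret) geometry on point clouds. Projection extremes over a
// direction set; since the width of a convex body equals the width of its
// point set, operating on boundary voxel centres (or on hull vertices
// extracted by cpp_support_extremes) is sufficient.

// widths[j] = max_i <p_i, u_j> - min_i <p_i, u_j>

// [[Rcpp::export]]
NumericVector cpp_feret_widths(NumericMatrix pts, NumericMatrix dirs) {
  int n = pts.nrow(), m = dirs.nrow();
  NumericVector w(m);
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0);
    py[i] = pts(i, 1);
    pz[i] = pts(i, 2);
  }
  for (int j = 0; j < m; ++j) {
    double ux = dirs(j, 0), uy = dirs(j, 1), uz = dirs(j, 2);
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double d = px[i] * ux + py[i] * uy + pz[i] * uz;
      if (d < lo) lo = d;
      if (d > hi) hi = d;
    }
    w[j] = hi - lo;
  }
  return w;
}

// 1-based indices of the argmax and argmin point for every direction
// (columns: max, min). The union over directions is a subset of the convex
// hull vertices (support points).

// [[Rcpp::export]]
IntegerMatrix cpp_support_extremes(NumericMatrix pts, NumericMatrix dirs) {
  int n = pts.nrow(), m = dirs.nrow();
  IntegerMatrix out(m, 2);
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0);
    py[i] = pts(i, 1);
    pz[i] = pts(i, 2);
  }
  for (int j = 0; j < m; ++j) {
    double ux = dirs(j, 0), uy = dirs(j, 1), uz = dirs(j, 2);
    double lo = R_PosInf, hi = R_NegInf;
    int ilo = 0, ihi = 0;
    for (int i = 0; i < n; ++i) {
      double d = px[i] * ux + py[i] * uy + pz[i] * uz;
      if (d > hi) {
        hi = d;
        ihi = i;
      }
      if (d < lo) {
        lo = d;
        ilo = i;
      }
    }
    out(j, 0) = ihi + 1;
    out(j, 1) = ilo + 1;
  }
  return out;
}

// Fill the sampled half-space intersection { x : <u_j, x> <= h_j } on a voxel
// grid. Because the region is convex, the feasible x-range in each (y, z)
// column is an interval, computed by clipping against every half-space.
// Coordinates: voxel (x,y,z) (0-based) sits at origin + voxel_size * (x,y,z).

// [[Rcpp::export]]
LogicalVector cpp_hull_fill(NumericMatrix dirs, NumericVector hvals,
                            IntegerVector dims, NumericVector origin,
                            double voxel_size) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int m = dirs.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const double eps = 1e-9 * voxel_size;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double Y = origin[1] + voxel_size * y;
      double Z = origin[2] + voxel_size * z;
      double xlo = origin[0], xhi = origin[0] + voxel_size * (nx - 1);
      bool empty = false;
      for (int j = 0; j < m && !empty; ++j) {
        double ux = dirs(j, 0);
        double rhs = hvals[j] - dirs(j, 1) * Y - dirs(j, 2) * Z;
        if (std::fabs(ux) <= 1e-12) {
          if (rhs < -eps) empty = true;
        } else if (ux > 0) {
          double b = rhs / ux;
          if (b < xhi) xhi = b;
        } else {
          double b = rhs / ux;
          if (b > xlo) xlo = b;
        }
      }
      if (empty || xhi < xlo - eps) continue;
      int ia = (int)std::ceil((xlo - origin[0] - eps) / voxel_size);
      int ib = (int)std::floor((xhi - origin[0] + eps) / voxel_size);
      if (ia < 0) ia = 0;
      if (ib >= nx) ib = nx - 1;
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = ia; x <= ib; ++x) out[base + x] = true;
    }
  return out;
}
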