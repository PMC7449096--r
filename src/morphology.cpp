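#include "grid.h"
#include <queue>
#include <cstdint>

using namespace Rcpp;

// ---- 3D connected-component labelling -------------------------------------
//
// Labels are assigned consecutively (1..n) in the order each component's
// first voxel appears in canonical linear scan order, which makes the
// labelling deterministic across runs and platforms.

// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims,
                          int connectivity) {
  Grid g(dims);
  std::vector<std::array<int, 3> > off = neighbour_offsets(connectivity);
  IntegerVector lab(g.n());
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < g.n(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int x = (int)(c % g.nx);
      R_xlen_t r = c / g.nx;
      int y = (int)(r % g.ny);
      int z = (int)(r / g.ny);
      for (size_t k = 0; k < off.size(); ++k) {
        int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
          continue;
        R_xlen_t t = g.idx(xx, yy, zz);
        if (mask[t] && !lab[t]) {
          lab[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// ---- border flood fill ------------------------------------------------------
//
// Reachability of voxels from the volume border without crossing `blocked`
// voxels. Used for hole filling (enclosed cavity = not blocked, not reached)
// and for the shell-integrity check.

// [[Rcpp::export]]
LogicalVector cpp_flood_from_border(LogicalVector blocked, IntegerVector dims,
                                    int connectivity) {
  Grid g(dims);
  std::vector<std::array<int, 3> > off = neighbour_offsets(connectivity);
  LogicalVector reached(g.n());
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        if (x > 0 && x < g.nx - 1 && y > 0 && y < g.ny - 1 && z > 0 &&
            z < g.nz - 1)
          continue;
        R_xlen_t s = g.idx(x, y, z);
        if (!blocked[s] && !reached[s]) {
          reached[s] = true;
          stack.push_back(s);
        }
      }
  while (!stack.empty()) {
    R_xlen_t c = stack.back();
    stack.pop_back();
    int x = (int)(c % g.nx);
    R_xlen_t r = c / g.nx;
    int y = (int)(r % g.ny);
    int z = (int)(r / g.ny);
    for (size_t k = 0; k < off.size(); ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
        continue;
      R_xlen_t t = g.idx(xx, yy, zz);
      if (!blocked[t] && !reached[t]) {
        reached[t] = true;
        stack.push_back(t);
      }
    }
  }
  return reached;
}

// ---- squared Euclidean distance transform ----------------------------------
//
// Separable lower-envelope-of-parabolas transform (exact squared EDT).
// Returns, for every TRUE voxel, the squared distance in voxel units to the
// nearest FALSE voxel (0 on FALSE voxels). If the mask has no FALSE voxel the
// result is a large sentinel (> any realistic grid diagonal).

static const double EDT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& zb, int n) {
  int k = 0;
  v[0] = 0;
  zb[0] = -EDT_INF;
  zb[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k] && k > 0) {
        --k;
      } else
        break;
    }
    if (s <= zb[k]) {  // k == 0 case: replace
      v[k] = q;
      zb[k] = -EDT_INF;
    } else {
      ++k;
      v[k] = q;
      zb[k] = s;
    }
    zb[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Axis passes are organised so the working set stays cache-resident:
// x lines are contiguous; y lines live inside one (x, y) plane; z lines are
// gathered into an (x, z) slab per y with contiguous x-runs.
static void edt_pass(std::vector<double>& vol, const Grid& g, int axis) {
  int len = axis == 0 ? g.nx : (axis == 1 ? g.ny : g.nz);
  std::vector<double> f(len), d(len), zb(len + 1);
  std::vector<int> v(len);
  if (axis == 0) {
    for (int z = 0; z < g.nz; ++z)
      for (int y = 0; y < g.ny; ++y) {
        double* line = &vol[g.idx(0, y, z)];
        for (int i = 0; i < len; ++i) f[i] = line[i];
        dt1d(f, d, v, zb, len);
        for (int i = 0; i < len; ++i) line[i] = d[i];
      }
  } else if (axis == 1) {
    for (int z = 0; z < g.nz; ++z) {
      double* plane = &vol[(R_xlen_t)g.nx * g.ny * z];
      for (int x = 0; x < g.nx; ++x) {
        for (int i = 0; i < len; ++i) f[i] = plane[x + (R_xlen_t)g.nx * i];
        dt1d(f, d, v, zb, len);
        for (int i = 0; i < len; ++i) plane[x + (R_xlen_t)g.nx * i] = d[i];
      }
    }
  } else {
    std::vector<double> slab((R_xlen_t)g.nx * g.nz);
    for (int y = 0; y < g.ny; ++y) {
      for (int z = 0; z < g.nz; ++z) {
        const double* run = &vol[g.idx(0, y, z)];
        std::copy(run, run + g.nx, &slab[(R_xlen_t)g.nx * z]);
      }
      for (int x = 0; x < g.nx; ++x) {
        for (int i = 0; i < len; ++i) f[i] = slab[x + (R_xlen_t)g.nx * i];
        dt1d(f, d, v, zb, len);
        for (int i = 0; i < len; ++i) slab[x + (R_xlen_t)g.nx * i] = d[i];
      }
      for (int z = 0; z < g.nz; ++z) {
        double* run = &vol[g.idx(0, y, z)];
        std::copy(&slab[(R_xlen_t)g.nx * z], &slab[(R_xlen_t)g.nx * (z + 1)],
                  run);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  std::vector<double> vol(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) vol[i] = mask[i] ? EDT_INF : 0.0;
  edt_pass(vol, g, 0);
  edt_pass(vol, g, 1);
  edt_pass(vol, g, 2);
  NumericVector out(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i) out[i] = vol[i];
  return out;
}

// ---- marker-based watershed -------------------------------------------------
//
// Priority-flood watershed: marker voxels are pushed with their own priority
// (typically a gradient magnitude or a negated distance transform); voxels are
// flooded in ascending priority, FIFO on ties, so the result is deterministic.

struct WsEntry {
  double p;
  uint64_t t;
  R_xlen_t i;
  int lab;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.p != b.p) return a.p > b.p;
    return a.t > b.t;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, IntegerVector markers,
                            LogicalVector mask, IntegerVector dims,
                            int connectivity) {
  Grid g(dims);
  std::vector<std::array<int, 3> > off = neighbour_offsets(connectivity);
  IntegerVector lab(g.n());
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> q;
  uint64_t tick = 0;
  for (R_xlen_t i = 0; i < g.n(); ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      WsEntry e = {priority[i], tick++, i, markers[i]};
      q.push(e);
    }
  }
  while (!q.empty()) {
    WsEntry e = q.top();
    q.pop();
    int x = (int)(e.i % g.nx);
    R_xlen_t r = e.i / g.nx;
    int y = (int)(r % g.ny);
    int z = (int)(r / g.ny);
    for (size_t k = 0; k < off.size(); ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
        continue;
      R_xlen_t t = g.idx(xx, yy, zz);
      if (mask[t] && lab[t] == 0) {
        lab[t] = e.lab;
        WsEntry ne = {priority[t], tick++, t, e.lab};
        q.push(ne);
      }
    }
  }
  return lab;
}

// ---- local thickness --------------------------------------------------------
//
// Inscribed-sphere (Hildebrand-Rueegsegger) local thickness: the thickness at
// a voxel is the diameter of the largest sphere fully inside the structure
// that contains the voxel. Spheres are seeded at distance-ridge voxels (local
// maxima of the squared EDT over the 26-neighbourhood) and painted in
// descending radius order. Result is in voxel units (isotropic grid).

// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dims) {
  Grid g(dims);
  NumericVector edt = cpp_edt_sq(mask, dims);
  std::vector<std::array<int, 3> > off = neighbour_offsets(26);

  // distance-ridge candidates
  std::vector<R_xlen_t> cand;
  for (R_xlen_t i = 0; i < g.n(); ++i) {
    if (!mask[i]) continue;
    int x = (int)(i % g.nx);
    R_xlen_t r = i / g.nx;
    int y = (int)(r % g.ny);
    int z = (int)(r / g.ny);
    bool ismax = true;
    for (size_t k = 0; k < off.size() && ismax; ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= g.nx || yy >= g.ny || zz >= g.nz)
        continue;
      if (edt[g.idx(xx, yy, zz)] > edt[i]) ismax = false;
    }
    if (ismax) cand.push_back(i);
  }
  std::sort(cand.begin(), cand.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (edt[a] != edt[b]) return edt[a] > edt[b];
    return a < b;
  });

  NumericVector th2(g.n());  // squared radius of the largest covering sphere
  for (size_t c = 0; c < cand.size(); ++c) {
    R_xlen_t i = cand[c];
    double r2 = edt[i];
    if (r2 <= 0) continue;
    double rad = std::sqrt(r2);
    int R = (int)std::floor(rad);
    int x0 = (int)(i % g.nx);
    R_xlen_t rr = i / g.nx;
    int y0 = (int)(rr % g.ny);
    int z0 = (int)(rr / g.ny);
    for (int dz = -R; dz <= R; ++dz) {
      int z = z0 + dz;
      if (z < 0 || z >= g.nz) continue;
      for (int dy = -R; dy <= R; ++dy) {
        int y = y0 + dy;
        if (y < 0 || y >= g.ny) continue;
        double dzy = (double)dz * dz + (double)dy * dy;
        if (dzy > r2) continue;
        int xr = (int)std::floor(std::sqrt(r2 - dzy));
        int xa = std::max(0, x0 - xr), xb = std::min(g.nx - 1, x0 + xr);
        R_xlen_t base = g.idx(0, y, z);
        for (int x = xa; x <= xb; ++x) {
          R_xlen_t t = base + x;
          if (mask[t] && th2[t] < r2) th2[t] = r2;
        }
      }
    }
  }
  NumericVector out(g.n());
  for (R_xlen_t i = 0; i < g.n(); ++i)
    out[i] = mask[i] ? 2.0 * std::sqrt(th2[i]) : 0.0;
  return out;
}
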