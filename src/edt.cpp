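#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Felzenszwalb & Huttenlocher separable squared Euclidean distance transform.
// Input: logical array (vector + dim); output: squared distance (in voxel
// units) from every voxel to the nearest TRUE voxel. Works for 2D by nz = 1.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  static std::vector<int> v;
  static std::vector<double> z;
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  v.assign(n, 0);
  z.assign(n + 1, 0.0);
  int k = 0;
  v[0] = q0; z[0] = -INF; z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;  // an infinite parabola never wins
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
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(const LogicalVector& feature, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim.size() > 1 ? dim[1] : 1,
            nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = feature[i] ? 0.0 : INF;
  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
      for (int x = 0; x < nx; ++x) f[x] = out[base + x];
      dt1d(f, d, nx);
      for (int x = 0; x < nx; ++x) out[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * z;
      for (int y = 0; y < ny; ++y) f[y] = out[base + (R_xlen_t)nx * y];
      dt1d(f, d, ny);
      for (int y = 0; y < ny; ++y) out[base + (R_xlen_t)nx * y] = d[y];
    }
  if (nz > 1) {
    f.resize(nz); d.resize(nz);
    const R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * y;
        for (int z = 0; z < nz; ++z) f[z] = out[base + plane * z];
        dt1d(f, d, nz);
        for (int z = 0; z < nz; ++z) out[base + plane * z] = d[z];
      }
  }
  return out;
}

// Local thickness by the maximal-inscribed-sphere method: thickness at x is
// the diameter 2*r(p) of the largest distance-transform sphere (centre p,
// radius r(p) = distance to background) that contains x. Every foreground
// voxel's sphere is painted, in decreasing radius order so already-saturated
// spheres can be skipped cheaply; the result is exact for centres on the
// voxel grid.
// [[Rcpp::export(name = ".local_thickness")]]
NumericVector local_thickness(const LogicalVector& mask,
                              const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim.size() > 2 ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector bg(n);
  for (R_xlen_t i = 0; i < n; ++i) bg[i] = !mask[i];
  NumericVector d2 = edt_sq(bg, dim);
  NumericVector th(n);
  std::vector<double> r(n);
  std::vector<R_xlen_t> order;
  order.reserve(n / 4);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i]) {
      r[i] = std::sqrt(d2[i]);
      th[i] = 2.0 * r[i];
      order.push_back(i);
    } else {
      r[i] = 0.0;
      th[i] = 0.0;
    }
  }
  std::sort(order.begin(), order.end(),
            [&](R_xlen_t a, R_xlen_t b) { return r[a] > r[b]; });
  for (R_xlen_t k = 0; k < (R_xlen_t)order.size(); ++k) {
    const R_xlen_t idx = order[k];
    const double rc = r[idx];
    if (rc < 1.0) continue;           // unit sphere covers only the centre
    const double diam = 2.0 * rc;
    const int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
    const int ri = (int)std::floor(rc);
    const double rc2 = rc * rc + 1e-9;
    bool useful = false;
    for (int dz = -ri; dz <= ri; ++dz) {
      int pz = z + dz;
      if (pz < 0 || pz >= nz) continue;
      for (int dy = -ri; dy <= ri; ++dy) {
        int py = y + dy;
        if (py < 0 || py >= ny) continue;
        double rem = rc2 - (double)dz * dz - (double)dy * dy;
        if (rem < 0) continue;
        int rx = (int)std::floor(std::sqrt(rem));
        int x0 = x - rx < 0 ? 0 : x - rx;
        int x1 = x + rx >= nx ? nx - 1 : x + rx;
        R_xlen_t base = (R_xlen_t)nx * (py + (R_xlen_t)ny * pz);
        for (int px = x0; px <= x1; ++px) {
          R_xlen_t q = base + px;
          if (mask[q] && th[q] < diam) { th[q] = diam; useful = true; }
        }
      }
    }
    (void)useful;
  }
  return th;
}
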