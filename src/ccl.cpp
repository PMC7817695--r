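#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling of a binary 2D image, 8-connectivity
// (the particle-analysis convention). Labels are 1..k in scan order of the
// first-visited pixel; 0 is background.
// [[Rcpp::export(name = ".cc_label2d")]]
IntegerMatrix cc_label2d(const LogicalMatrix& mask, const int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const bool diag = connectivity == 8;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            if (!diag && di != 0 && dj != 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// 3D labelling with 26-connectivity on a logical array given as a vector
// with dims (nx, ny, nz) in R array order.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(const LogicalVector& mask, const IntegerVector& dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int x = idx % nx, y = (idx / nx) % ny, z = idx / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int px = x + dx, py = y + dy, pz = z + dz;
            if (px < 0 || py < 0 || pz < 0 || px >= nx || py >= ny || pz >= nz)
              continue;
            R_xlen_t q = px + (R_xlen_t)nx * (py + (R_xlen_t)ny * pz);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Outer-boundary perimeter of each labelled particle by Moore-neighbour
// tracing: straight steps weigh 1, diagonal steps sqrt(2). Single-pixel
// particles are assigned the boundary of a unit square (4).
// [[Rcpp::export(name = ".cc_perimeters")]]
NumericVector cc_perimeters(const IntegerMatrix& lab, const int n_labels) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(n_labels);
  std::vector<int> starti(n_labels, -1), startj(n_labels, -1);
  // first pixel of each label in column-major scan = uppermost-leftmost
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l > 0 && starti[l - 1] < 0) { starti[l - 1] = i; startj[l - 1] = j; }
    }
  // Moore neighbourhood in clockwise order starting from "west"
  const int mi[8] = { 0, -1, -1, -1,  0,  1, 1, 1};
  const int mj[8] = {-1, -1,  0,  1,  1,  1, 0, -1};
  const double w[8] = {1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2, 1, M_SQRT2};
  for (int l = 0; l < n_labels; ++l) {
    const int si = starti[l], sj = startj[l];
    if (si < 0) continue;
    // find first neighbour clockwise from west
    int dir = -1;
    for (int k = 0; k < 8; ++k) {
      int ni = si + mi[k], nj = sj + mj[k];
      if (ni >= 0 && nj >= 0 && ni < nr && nj < nc && lab(ni, nj) == l + 1) {
        dir = k; break;
      }
    }
    if (dir < 0) { per[l] = 4.0; continue; }  // isolated pixel
    double p = 0.0;
    int ci = si, cj = sj;
    int backtrack = (dir + 4) % 8;  // direction we came from
    int firsti = -1, firstj = -1, firstdir = -1;
    int guard = 8 * nr * nc;
    while (guard-- > 0) {
      // search clockwise starting just after the backtrack direction
      int k = (backtrack + 1) % 8, found = -1;
      for (int t = 0; t < 8; ++t) {
        int kk = (k + t) % 8;
        int ni = ci + mi[kk], nj = cj + mj[kk];
        if (ni >= 0 && nj >= 0 && ni < nr && nj < nc && lab(ni, nj) == l + 1) {
          found = kk; break;
        }
      }
      int ni = ci + mi[found], nj = cj + mj[found];
      p += w[found];
      // Jacob's stopping criterion: stop when the start pixel is re-entered
      // from the same predecessor and direction; the perimeter is the step
      // weight accumulated over that one full loop.
      if (ni == si && nj == sj) {
        if (firstdir < 0) { firsti = ci; firstj = cj; firstdir = found; p = 0.0; }
        else if (ci == firsti && cj == firstj && found == firstdir) break;
      }
      backtrack = (found + 4) % 8;
      ci = ni; cj = nj;
    }
    per[l] = p;
  }
  return per;
}
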