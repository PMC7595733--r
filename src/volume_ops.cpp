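#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear index helpers for a 3D array stored in R's column-major order:
// idx = i + n1 * (j + n2 * k), all 0-based.

// Label connected foreground components of a 3D logical mask.
// connectivity: 6 (face) or 26 (face+edge+corner). Returns 0 for background,
// 1..n_components for foreground, components numbered in scan order.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  // neighbour offsets
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && (std::abs(a) + std::abs(b) + std::abs(c)) != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int noff = (int)di.size();

  IntegerVector labels(n, 0);
  int current = 0;
  std::vector<R_xlen_t> stack;
  stack.reserve(1024);

  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || labels[s] != 0) continue;
    ++current;
    labels[s] = current;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int k = (int)(v / ((R_xlen_t)n1 * n2));
      int rem = (int)(v - (R_xlen_t)k * n1 * n2);
      int j = rem / n1;
      int i = rem - j * n1;
      for (int o = 0; o < noff; ++o) {
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3) continue;
        R_xlen_t w = ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("n_components") = current;
  return labels;
}

// Binary dilation/erosion with a Euclidean ball of given radius (in voxel
// index units, isotropic in index space).
// [[Rcpp::export(name = ".ball_morph_3d")]]
LogicalVector ball_morph_3d(LogicalVector mask, IntegerVector dims, double radius,
                            bool dilate) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != n) stop("mask length does not match dims");
  if (radius < 0) stop("radius must be >= 0");

  std::vector<int> di, dj, dk;
  int r = (int)std::floor(radius);
  double r2 = radius * radius;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      for (int c = -r; c <= r; ++c)
        if ((double)(a * a + b * b + c * c) <= r2) {
          di.push_back(a); dj.push_back(b); dk.push_back(c);
        }
  const int noff = (int)di.size();

  LogicalVector out(n);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        bool acc = !dilate;  // erode: AND starts true; dilate: OR starts false
        for (int o = 0; o < noff; ++o) {
          int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
          bool v;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
            v = false;  // outside grid counts as background
          else
            v = mask[ii + (R_xlen_t)n1 * (jj + (R_xlen_t)n2 * kk)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = acc;
      }
  return out;
}

// Classic non-local means on a single 2D slice. patch_r: patch half-width,
// search_r: search window half-width, h: filtering strength (grey levels).
// Edge patches are clamped (replicate padding). The centre pixel gets the
// maximum weight observed among its neighbours (standard self-weight rule).
// [[Rcpp::export(name = ".nlm_slice")]]
NumericMatrix nlm_slice(NumericMatrix img, int patch_r, int search_r, double h) {
  const int nr = img.nrow(), nc = img.ncol();
  if (h <= 0) return clone(img);
  NumericMatrix out(nr, nc);
  const double h2 = h * h;
  const int psz = (2 * patch_r + 1) * (2 * patch_r + 1);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double wsum = 0.0, acc = 0.0, wmax = 0.0;
      for (int dj = -search_r; dj <= search_r; ++dj) {
        for (int di = -search_r; di <= search_r; ++di) {
          if (di == 0 && dj == 0) continue;
          int ci = i + di, cj = j + dj;
          if (ci < 0 || ci >= nr || cj < 0 || cj >= nc) continue;
          // patch distance
          double d2 = 0.0;
          for (int pj = -patch_r; pj <= patch_r; ++pj) {
            for (int pi = -patch_r; pi <= patch_r; ++pi) {
              int a1 = std::min(std::max(i + pi, 0), nr - 1);
              int b1 = std::min(std::max(j + pj, 0), nc - 1);
              int a2 = std::min(std::max(ci + pi, 0), nr - 1);
              int b2 = std::min(std::max(cj + pj, 0), nc - 1);
              double d = img(a1, b1) - img(a2, b2);
              d2 += d * d;
            }
          }
          d2 /= psz;
          double w = std::exp(-d2 / h2);
          if (w > wmax) wmax = w;
          wsum += w;
          acc += w * img(ci, cj);
        }
      }
      if (wmax <= 0) wmax = 1.0;
      wsum += wmax;
      acc += wmax * img(i, j);
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
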