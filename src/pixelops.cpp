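#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zhang-Suen thinning of a binary mask (column-major R matrix of 0/1).
// Returns a mask of the same shape holding the 8-connected skeleton.
// [[Rcpp::export(name = ".thin_mask")]]
IntegerMatrix thin_mask(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img(clone(mask));
  std::vector<std::pair<int, int> > kill;
  kill.reserve(256);
  bool changed = true;
  // neighbours P2..P9 clockwise from north (row-1,col)
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img(i, j)) continue;
          int p[8];
          for (int k = 0; k < 8; ++k) {
            int r = i + dr[k], c = j + dc[k];
            p[k] = (r >= 0 && r < nr && c >= 0 && c < nc) ? img(r, c) : 0;
          }
          int b = 0, a = 0;
          for (int k = 0; k < 8; ++k) {
            b += p[k];
            if (!p[k] && p[(k + 1) % 8]) ++a;
          }
          if (b < 2 || b > 6 || a != 1) continue;
          bool cond;
          if (pass == 0)  // P2*P4*P6 == 0 and P4*P6*P8 == 0
            cond = !(p[0] && p[2] && p[4]) && !(p[2] && p[4] && p[6]);
          else            // P2*P4*P8 == 0 and P2*P6*P8 == 0
            cond = !(p[0] && p[2] && p[6]) && !(p[0] && p[4] && p[6]);
          if (cond) kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k].first, kill[k].second) = 0;
    }
  }
  return img;
}

// 8-connected component labelling by iterative flood fill.
// Returns an integer matrix of labels (0 = background, 1..n components).
// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r = ci + dr[k], c = cj + dc[k];
          if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
          if (mask(r, c) && !lab(r, c)) {
            lab(r, c) = next;
            stack.push_back(r + c * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Stamp filled discs onto a logical canvas: centres (row, col) in 0-based
// pixel coordinates, per-disc radius in pixels. Used by the synthetic
// plate renderer so the rasterized mask is exact (no anti-aliasing).
// [[Rcpp::export(name = ".stamp_discs")]]
LogicalMatrix stamp_discs(LogicalMatrix canvas, NumericVector row0,
                          NumericVector col0, NumericVector radius) {
  int nr = canvas.nrow(), nc = canvas.ncol();
  for (int k = 0; k < row0.size(); ++k) {
    double cr = row0[k], cc = col0[k], rad = radius[k];
    if (rad <= 0) continue;
    int r1 = std::max(0, (int)std::floor(cr - rad));
    int r2 = std::min(nr - 1, (int)std::ceil(cr + rad));
    int c1 = std::max(0, (int)std::floor(cc - rad));
    int c2 = std::min(nc - 1, (int)std::ceil(cc + rad));
    double rad2 = rad * rad;
    for (int c = c1; c <= c2; ++c) {
      double dc = c - cc;
      for (int r = r1; r <= r2; ++r) {
        double dr = r - cr;
        if (dr * dr + dc * dc <= rad2) canvas(r, c) = true;
      }
    }
  }
  return canvas;
}
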