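// Low-level raster kernels for creek-network extraction.
//
// All routines operate on R matrices (column-major). Coordinates are
// (row, col), 1-based on the R side, with row 1 the northernmost row.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform with argmin.
//
// For every cell, finds the nearest `feature` cell in exact Euclidean
// pixel distance. Ties are broken lexicographically by (row, col) of the
// feature cell, so the result is fully deterministic. Returns squared
// distances (exact integers in double) and the 1-based linear index
// (column-major, as R matrices use) of the chosen feature cell.
//
// Method: per-column sorted lists of feature rows; for each target cell,
// scan columns outward while the column offset alone can still beat or
// tie the current best squared distance. Exact, no grid-propagation
// approximation.
// [[Rcpp::export]]
List edt_nearest_cpp(LogicalMatrix feature) {
  const int nr = feature.nrow(), nc = feature.ncol();
  std::vector< std::vector<int> > rows_by_col(nc);
  long nfeat = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (feature(r, c)) { rows_by_col[c].push_back(r); ++nfeat; }
  NumericMatrix d2(nr, nc);
  IntegerMatrix idx(nr, nc);
  if (nfeat == 0) {
    std::fill(d2.begin(), d2.end(), R_PosInf);
    std::fill(idx.begin(), idx.end(), NA_INTEGER);
    return List::create(_["dist2"] = d2, _["index"] = idx);
  }
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      double best = R_PosInf;
      int best_r = -1, best_c = -1;
      for (int dc = 0; dc < nc; ++dc) {
        double dc2 = (double)dc * dc;
        if (best_r >= 0 && dc2 > best) break;
        for (int sgn = 0; sgn < 2; ++sgn) {
          if (sgn == 1 && dc == 0) continue;
          int c = (sgn == 0) ? c0 + dc : c0 - dc;
          if (c < 0 || c >= nc) continue;
          const std::vector<int>& fr = rows_by_col[c];
          if (fr.empty()) continue;
          // nearest feature row to r0 (binary search), prefer smaller row
          std::vector<int>::const_iterator it =
            std::lower_bound(fr.begin(), fr.end(), r0);
          for (int k = 0; k < 2; ++k) {
            int r;
            if (k == 0) { if (it == fr.begin()) continue; r = *(it - 1); }
            else        { if (it == fr.end())   continue; r = *it; }
            double dd = dc2 + (double)(r - r0) * (r - r0);
            if (dd < best ||
                (dd == best && (r < best_r || (r == best_r && c < best_c)))) {
              best = dd; best_r = r; best_c = c;
            }
          }
        }
      }
      d2(r0, c0) = best;
      idx(r0, c0) = best_c * nr + best_r + 1;  // 1-based linear index
    }
  }
  return List::create(_["dist2"] = d2, _["index"] = idx);
}

// 8-connected component labelling, deterministic label order: components
// numbered by first (row-major: by row, then column) pixel encountered.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next_lab = 0;
  std::vector<int> stack;
  for (int r0 = 0; r0 < nr; ++r0) {
    for (int c0 = 0; c0 < nc; ++c0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next_lab;
      stack.push_back(c0 * nr + r0);
      lab(r0, c0) = next_lab;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int r = p % nr, c = p / nr;
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next_lab;
              stack.push_back(cc * nr + rr);
            }
          }
      }
    }
  }
  return lab;
}

// ---- thinning ------------------------------------------------------------

// Neighbour order p2..p9 clockwise from north:
// p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW. Off-grid = 0.
static inline void nbrs8(const LogicalMatrix& img, int r, int c, int p[8]) {
  const int nr = img.nrow(), nc = img.ncol();
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int k = 0; k < 8; ++k) {
    int rr = r + dr[k], cc = c + dc[k];
    p[k] = (rr >= 0 && rr < nr && cc >= 0 && cc < nc && img(rr, cc)) ? 1 : 0;
  }
}


// True when the pixel is 8-simple and not an endpoint: its foreground
// 8-neighbours form exactly one 8-connected component within the ring and
// at least one orthogonal neighbour is background. Such a pixel can be
// deleted without changing connectivity, holes, endpoints or loops.
static bool redundant_simple(const LogicalMatrix& img, int r, int c) {
  int p[8];
  nbrs8(img, r, c, p);
  int B = 0;
  for (int k = 0; k < 8; ++k) B += p[k];
  if (B < 2 || B > 7) return false;
  if (p[0] && p[2] && p[4] && p[6]) return false;  // no orthogonal background
  // exact count of 8-connected components among the foreground ring
  // positions (note W and N touch diagonally even though they are two
  // steps apart on the ring)
  static const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  static const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int comp[8];
  for (int i = 0; i < 8; ++i) comp[i] = -1;
  int ncomp = 0;
  for (int i = 0; i < 8; ++i) {
    if (!p[i] || comp[i] != -1) continue;
    comp[i] = ncomp;
    int st[8], top = 0;
    st[top++] = i;
    while (top) {
      int a = st[--top];
      for (int b = 0; b < 8; ++b) {
        if (!p[b] || comp[b] != -1) continue;
        if (std::abs(dr[a] - dr[b]) <= 1 && std::abs(dc[a] - dc[b]) <= 1) {
          comp[b] = ncomp;
          st[top++] = b;
        }
      }
    }
    ++ncomp;
  }
  return ncomp == 1;
}

// Topology-preserving directional thinning (Zhang–Suen class).
//
// Each iteration runs four directional sub-passes (north, south, east,
// west). A sub-pass snapshots the pixels whose neighbour in that
// direction is background and which are 8-simple non-endpoints, then
// deletes them sequentially in row-major order, re-verifying simplicity
// against the current image before each deletion. The snapshot bounds
// erosion to one boundary layer per sub-pass (so ribbons shrink to their
// centreline instead of being consumed), while sequential simple-point
// deletion preserves connectivity, holes and endpoints exactly. A final
// clean-up removes the staircase/corner redundancies the directional
// passes leave, yielding a strictly one-pixel-wide skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_skeleton_cpp(LogicalMatrix mask) {
  LogicalMatrix img = clone(mask);
  const int nr = img.nrow(), nc = img.ncol();
  // direction order N, S, E, W keeps the result centred
  const int ddr[4] = {-1, 1, 0, 0};
  const int ddc[4] = {0, 0, 1, -1};
  bool changed = true;
  std::vector<int> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      cand.clear();
      for (int r = 0; r < nr; ++r)
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int rr = r + ddr[d], cc = c + ddc[d];
          bool bg = (rr < 0 || rr >= nr || cc < 0 || cc >= nc ||
                     !img(rr, cc));
          if (bg && redundant_simple(img, r, c))
            cand.push_back(c * nr + r);
        }
      for (size_t i = 0; i < cand.size(); ++i) {
        int r = cand[i] % nr, c = cand[i] / nr;
        if (redundant_simple(img, r, c)) {  // re-check on current image
          img(r, c) = false;
          changed = true;
        }
      }
    }
  }
  // Redundancy clean-up: sequentially delete 8-simple non-endpoint pixels.
  // A pixel is removable when its foreground 8-neighbours form a single
  // 8-connected arc and it has at least one orthogonal background
  // neighbour (so no 4-hole is created). This removes the staircase and
  // corner artifacts the directional sub-iterations leave behind while
  // provably preserving connectivity, endpoints and loops.
  bool again = true;
  while (again) {
    again = false;
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nc; ++c) {
        if (!img(r, c)) continue;
        if (redundant_simple(img, r, c)) {
          img(r, c) = false;
          again = true;
        }
      }
  }
  return img;
}

// Count of 8-neighbours for every true cell (0 elsewhere).
// [[Rcpp::export]]
IntegerMatrix neighbour_count_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix deg(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) { deg(r, c) = 0; continue; }
      int p[8];
      nbrs8(mask, r, c, p);
      int B = 0;
      for (int k = 0; k < 8; ++k) B += p[k];
      deg(r, c) = B;
    }
  return deg;
}

// Bresenham raster line between two cells, endpoints included.
// Returns an n x 2 matrix of 1-based (row, col).
// [[Rcpp::export]]
IntegerMatrix bresenham_cpp(int r0, int c0, int r1, int c1) {
  std::vector<int> rr, cc;
  int dr = std::abs(r1 - r0), dc = std::abs(c1 - c0);
  int sr = (r0 < r1) ? 1 : -1, sc = (c0 < c1) ? 1 : -1;
  int err = dc - dr, r = r0, c = c0;
  while (true) {
    rr.push_back(r); cc.push_back(c);
    if (r == r1 && c == c1) break;
    int e2 = 2 * err;
    if (e2 > -dr) { err -= dr; c += sc; }
    if (e2 < dc)  { err += dc; r += sr; }
  }
  IntegerMatrix out(rr.size(), 2);
  for (size_t i = 0; i < rr.size(); ++i) {
    out(i, 0) = rr[i];
    out(i, 1) = cc[i];
  }
  return out;
}
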