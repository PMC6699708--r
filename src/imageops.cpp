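#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binary image ops on H x W logical matrices (column-major, as stored by R).
// Foreground = true. All routines are deterministic and allocation-light;
// they back the segmentation and morphology feature modules.

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DR4[4] = {-1, 0, 0, 1};
static const int DC4[4] = {-1, 1, -1, 0}; // unused slot pattern kept simple

// [[Rcpp::export(name = "cpp_label")]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int nn = (connectivity == 8) ? 8 : 4;
  static const int dr4[4] = {-1, 1, 0, 0};
  static const int dc4[4] = {0, 0, -1, 1};
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * H);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % H, cc = idx / H;
        for (int k = 0; k < nn; ++k) {
          int rr = cr + ((nn == 8) ? DR8[k] : dr4[k]);
          int cw = cc + ((nn == 8) ? DC8[k] : dc4[k]);
          if (rr < 0 || rr >= H || cw < 0 || cw >= W) continue;
          if (mask(rr, cw) && lab(rr, cw) == 0) {
            lab(rr, cw) = next;
            stack.push_back(rr + cw * H);
          }
        }
      }
    }
  }
  return lab;
}

// Fill background components (4-connected) that do not touch the image
// border and are smaller than min_hole_area.
// [[Rcpp::export(name = "cpp_fill_holes")]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask, double min_hole_area) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix inv(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      inv(r, c) = !mask(r, c);
  IntegerMatrix lab = cpp_label(inv, 4);
  int nlab = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (lab(r, c) > nlab) nlab = lab(r, c);
  std::vector<double> size(nlab + 1, 0.0);
  std::vector<bool> border(nlab + 1, false);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      size[l] += 1.0;
      if (r == 0 || r == H - 1 || c == 0 || c == W - 1) border[l] = true;
    }
  }
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int l = lab(r, c);
      bool fg = mask(r, c);
      if (l > 0 && !border[l] && size[l] < min_hole_area) fg = true;
      out(r, c) = fg;
    }
  }
  return out;
}

// offsets: k x 2 matrix of (dr, dc) defining the structuring element.
// [[Rcpp::export(name = "cpp_erode")]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, const IntegerMatrix& offsets) {
  const int H = mask.nrow(), W = mask.ncol(), K = offsets.nrow();
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c)) { out(r, c) = false; continue; }
      bool all_in = true;
      for (int k = 0; k < K && all_in; ++k) {
        int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
        if (rr < 0 || rr >= H || cc < 0 || cc >= W || !mask(rr, cc)) all_in = false;
      }
      out(r, c) = all_in;
    }
  }
  return out;
}

// [[Rcpp::export(name = "cpp_dilate")]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, const IntegerMatrix& offsets) {
  const int H = mask.nrow(), W = mask.ncol(), K = offsets.nrow();
  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      bool any_in = false;
      for (int k = 0; k < K && !any_in; ++k) {
        int rr = r + offsets(k, 0), cc = c + offsets(k, 1);
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc)) any_in = true;
      }
      out(r, c) = any_in;
    }
  }
  return out;
}

// Moore-neighbour boundary tracing (clockwise) with Jacob's stopping
// criterion. Expects a single 8-connected foreground component; returns an
// ordered n x 2 matrix of (row, col), 1-based, tracing the outer contour.
// [[Rcpp::export(name = "cpp_boundary")]]
IntegerMatrix cpp_boundary(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // clockwise Moore neighbourhood starting at W (west)
  static const int mdr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int mdc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  int sr = -1, sc = -1;
  for (int r = 0; r < H && sr < 0; ++r)      // raster scan: top row first
    for (int c = 0; c < W; ++c)
      if (mask(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) stop("empty mask: no boundary to trace");
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  // backtrack starts at the west neighbour (background by scan order)
  int pr = sr, pc = sc;
  int bdir = 0; // index into moore order pointing at current backtrack
  const long maxit = 4L * (long)H * (long)W + 16;
  int first_dir = -1;
  long it = 0;
  while (it++ < maxit) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int dir = (bdir + k) % 8;
      int rr = pr + mdr[dir], cc = pc + mdc[dir];
      if (rr >= 0 && rr < H && cc >= 0 && cc < W && mask(rr, cc)) { found = dir; break; }
    }
    if (found < 0) break; // isolated pixel
    if (pr == sr && pc == sc) {
      if (first_dir < 0) first_dir = found;
      else if (found == first_dir && rows.size() > 1) break; // Jacob's criterion
    }
    int nr = pr + mdr[found], nc = pc + mdc[found];
    // new backtrack: the neighbour just before `found`, seen from the new pixel
    int prev = (found + 7) % 8;
    int br = pr + mdr[prev], bc = pc + mdc[prev];
    // direction from new pixel back to that background cell
    bdir = 0;
    for (int k = 0; k < 8; ++k)
      if (nr + mdr[k] == br && nc + mdc[k] == bc) { bdir = k; break; }
    pr = nr; pc = nc;
    if (pr == sr && pc == sc) {
      // arrived back at start; loop once more to check Jacob's criterion
      if ((long)rows.size() > 2L * (long)(H + W) * 4L) break;
    } else {
      rows.push_back(pr); cols.push_back(pc);
    }
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}

// Accumulate gray-level co-occurrence counts. `q` holds quantized levels
// 0..levels-1 with NA_INTEGER outside the region of interest. One count
// matrix per (dr, dc) offset; symmetrization/normalization happen in R.
// [[Rcpp::export(name = "cpp_glcm")]]
NumericVector cpp_glcm(const IntegerMatrix& q, int levels,
                       const IntegerVector& dr, const IntegerVector& dc) {
  const int H = q.nrow(), W = q.ncol(), A = dr.size();
  NumericVector out(Dimension(levels, levels, A));
  for (int a = 0; a < A; ++a) {
    const int drr = dr[a], dcc = dc[a];
    double* slab = &out[(size_t)a * levels * levels];
    for (int c = 0; c < W; ++c) {
      int cc = c + dcc;
      if (cc < 0 || cc >= W) continue;
      for (int r = 0; r < H; ++r) {
        int v1 = q(r, c);
        if (v1 == NA_INTEGER) continue;
        int rr = r + drr;
        if (rr < 0 || rr >= H) continue;
        int v2 = q(rr, cc);
        if (v2 == NA_INTEGER) continue;
        slab[v1 + (size_t)v2 * levels] += 1.0;
      }
    }
  }
  return out;
}
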