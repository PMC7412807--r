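// Low-level image and network kernels.
//
// Conventions shared with the R side:
//  * images are column-major R arrays, dim (H, W) or (H, W, C);
//  * activation tensors for the network are matrices with rows indexed by
//    (i, j, n) as r = i + H*j + H*W*n and one column per channel;
//  * binary masks are integer matrices with values {0, 1}.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// CLAHE on one 8-bit channel (values 0..255, stored as doubles).
//
// Per-tile 256-bin histograms are clipped at `clip` times the uniform level,
// the excess is redistributed uniformly, and the tile mapping is the
// midpoint-CDF lookup table scaled to [0, 255] (the midpoint convention maps
// a flat histogram to the identity, so constant inputs stay constant).
// Pixel values are interpolated bilinearly between the four surrounding tile
// mappings; tiles need not divide the image size evenly.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(const NumericMatrix& img, int ntiles_x, int ntiles_y,
                        double clip) {
  const int H = img.nrow(), W = img.ncol(), B = 256;
  const int ny = std::min(ntiles_y, H), nx = std::min(ntiles_x, W);
  std::vector<int> r0(ny + 1), c0(nx + 1);
  for (int t = 0; t <= ny; ++t) r0[t] = (int)std::floor((double)t * H / ny);
  for (int t = 0; t <= nx; ++t) c0[t] = (int)std::floor((double)t * W / nx);
  std::vector<double> cy(ny), cx(nx);
  for (int t = 0; t < ny; ++t) cy[t] = 0.5 * (r0[t] + r0[t + 1] - 1);
  for (int t = 0; t < nx; ++t) cx[t] = 0.5 * (c0[t] + c0[t + 1] - 1);

  std::vector<std::vector<double>> lut((size_t)ny * nx,
                                       std::vector<double>(B, 0.0));
  for (int ty = 0; ty < ny; ++ty) {
    for (int tx = 0; tx < nx; ++tx) {
      std::vector<double> hist(B, 0.0);
      long n = 0;
      for (int c = c0[tx]; c < c0[tx + 1]; ++c)
        for (int r = r0[ty]; r < r0[ty + 1]; ++r) {
          int v = (int)std::lround(img(r, c));
          v = std::min(255, std::max(0, v));
          hist[v] += 1.0;
          ++n;
        }
      double climit = std::max(clip * (double)n / B, 1.0);
      double excess = 0.0;
      for (int b = 0; b < B; ++b)
        if (hist[b] > climit) { excess += hist[b] - climit; hist[b] = climit; }
      double add = excess / B;
      double cum = 0.0;
      std::vector<double>& L = lut[(size_t)ty * nx + tx];
      for (int b = 0; b < B; ++b) {
        double h = hist[b] + add;
        L[b] = 255.0 * (cum + h / 2.0) / (double)n;
        cum += h;
      }
    }
  }

  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c) {
    int tx0, tx1; double wx;
    if (nx == 1 || c <= cx[0])        { tx0 = tx1 = 0;       wx = 0.0; }
    else if (c >= cx[nx - 1])         { tx0 = tx1 = nx - 1;  wx = 0.0; }
    else {
      tx0 = 0;
      while (tx0 + 1 < nx && cx[tx0 + 1] <= c) ++tx0;
      tx1 = tx0 + 1;
      wx = (c - cx[tx0]) / (cx[tx1] - cx[tx0]);
    }
    for (int r = 0; r < H; ++r) {
      int ty0, ty1; double wy;
      if (ny == 1 || r <= cy[0])      { ty0 = ty1 = 0;       wy = 0.0; }
      else if (r >= cy[ny - 1])       { ty0 = ty1 = ny - 1;  wy = 0.0; }
      else {
        ty0 = 0;
        while (ty0 + 1 < ny && cy[ty0 + 1] <= r) ++ty0;
        ty1 = ty0 + 1;
        wy = (r - cy[ty0]) / (cy[ty1] - cy[ty0]);
      }
      int v = (int)std::lround(img(r, c));
      v = std::min(255, std::max(0, v));
      double v00 = lut[(size_t)ty0 * nx + tx0][v];
      double v01 = lut[(size_t)ty0 * nx + tx1][v];
      double v10 = lut[(size_t)ty1 * nx + tx0][v];
      double v11 = lut[(size_t)ty1 * nx + tx1][v];
      double val = (1 - wy) * ((1 - wx) * v00 + wx * v01) +
                   wy * ((1 - wx) * v10 + wx * v11);
      out(r, c) = std::min(255.0, std::max(0.0, val));
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-channel median filter, k x k window (k odd), edge-replicated borders.
// [[Rcpp::export]]
NumericVector cpp_median_filter(const NumericVector& x, int H, int W, int C,
                                int k) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const int half = k / 2;
  std::vector<double> buf((size_t)k * k);
  for (int ch = 0; ch < C; ++ch) {
    const long off = (long)ch * H * W;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        size_t m = 0;
        for (int dj = -half; dj <= half; ++dj) {
          int jj = std::min(W - 1, std::max(0, j + dj));
          for (int di = -half; di <= half; ++di) {
            int ii = std::min(H - 1, std::max(0, i + di));
            buf[m++] = x[off + ii + (long)H * jj];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
        out[off + i + (long)H * j] = buf[m / 2];
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Binary erosion / dilation with a kh x kw rectangular structuring element.
// Anchor convention for even sizes: the element covers row offsets
// -(kh/2) .. kh-1-(kh/2) (OpenCV default anchor). Dilation scans the
// reflected element so that erode-then-dilate is a true Minkowski opening.
// Outside the frame counts as background.
// [[Rcpp::export]]
IntegerMatrix cpp_erode(const IntegerMatrix& m, int kh, int kw) {
  const int H = m.nrow(), W = m.ncol();
  const int up = kh / 2, down = kh - 1 - kh / 2;
  const int left = kw / 2, right = kw - 1 - kw / 2;
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int keep = 1;
      for (int dj = -left; dj <= right && keep; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= W) { keep = 0; break; }
        for (int di = -up; di <= down; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= H || m(ii, jj) == 0) { keep = 0; break; }
        }
      }
      out(i, j) = keep;
    }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_dilate(const IntegerMatrix& m, int kh, int kw) {
  const int H = m.nrow(), W = m.ncol();
  // reflected element: offsets -(kh-1-kh/2) .. kh/2
  const int up = kh - 1 - kh / 2, down = kh / 2;
  const int left = kw - 1 - kw / 2, right = kw / 2;
  IntegerMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int hit = 0;
      for (int dj = -left; dj <= right && !hit; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= W) continue;
        for (int di = -up; di <= down; ++di) {
          int ii = i + di;
          if (ii >= 0 && ii < H && m(ii, jj) != 0) { hit = 1; break; }
        }
      }
      out(i, j) = hit;
    }
  return out;
}

// ---------------------------------------------------------------------------
// 8-connected component labelling (iterative flood fill). Labels are 1..n in
// order of first encounter in a column-major raster scan.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& m) {
  const int H = m.nrow(), W = m.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (m(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [r, c] = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int rr = r + di, cc = c + dj;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (m(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back({rr, cc});
            }
          }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Outer-boundary perimeter of each labelled component by Moore-neighbour
// tracing; axis steps count 1, diagonal steps sqrt(2). Single pixels have
// perimeter 0.
static const int DR[8] = {0, -1, -1, -1, 0, 1, 1, 1};   // W NW N NE E SE S SW
static const int DC[8] = {-1, -1, 0, 1, 1, 1, 0, -1};   // clockwise

// [[Rcpp::export]]
NumericVector cpp_perimeter(const IntegerMatrix& lab, int nlab) {
  const int H = lab.nrow(), W = lab.ncol();
  NumericVector per(nlab);
  std::vector<int> sr(nlab, -1), sc(nlab, -1);
  // first pixel of each label in row-major order (top-left-most row, then col)
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      int l = lab(i, j);
      if (l > 0 && sr[l - 1] < 0) { sr[l - 1] = i; sc[l - 1] = j; }
    }
  const double SQ2 = std::sqrt(2.0);
  for (int l = 0; l < nlab; ++l) {
    if (sr[l] < 0) { per[l] = NA_REAL; continue; }
    int r = sr[l], c = sc[l];
    auto fg = [&](int rr, int cc) {
      return rr >= 0 && rr < H && cc >= 0 && cc < W && lab(rr, cc) == l + 1;
    };
    bool isolated = true;
    for (int d = 0; d < 8; ++d)
      if (fg(r + DR[d], c + DC[d])) { isolated = false; break; }
    if (isolated) { per[l] = 0.0; continue; }
    // backtrack starts at the W neighbour (background by the raster scan)
    int br = r, bc = c - 1;
    const int r0 = r, c0 = c, br0 = br, bc0 = bc;
    double total = 0.0;
    long cap = 4L * H * W + 8, steps = 0;
    while (steps++ < cap) {
      // direction index of the backtrack cell relative to the current pixel
      int db = 0;
      for (int d = 0; d < 8; ++d)
        if (r + DR[d] == br && c + DC[d] == bc) { db = d; break; }
      int found = -1;
      for (int i8 = 1; i8 <= 8; ++i8) {
        int d = (db + i8) % 8;
        if (fg(r + DR[d], c + DC[d])) { found = d; break; }
      }
      if (found < 0) break;  // cannot happen: not isolated
      total += (DR[found] != 0 && DC[found] != 0) ? SQ2 : 1.0;
      // new backtrack = the cell checked just before the hit (background,
      // adjacent to both the old and the new pixel)
      int prev = (found + 7) % 8;
      br = r + DR[prev]; bc = c + DC[prev];
      r += DR[found]; c += DC[found];
      if (r == r0 && c == c0 && br == br0 && bc == bc0) break;  // Jacob stop
    }
    per[l] = total;
  }
  return per;
}

// ---------------------------------------------------------------------------
// Network kernels. X is ((H*W*N) x C) with row index r = i + H*j + H*W*n.

// im2col for 3x3 (or k x k) same-padding stride-1 convolution:
// output ((H*W*N) x (k*k*C)), column index q = di + k*dj + k*k*ch with
// di, dj in 0..k-1 sampling input position (i + di - pad, j + dj - pad).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& X, int H, int W, int N, int k,
                         int pad) {
  const int C = X.ncol();
  const long HW = (long)H * W, rows = HW * N;
  NumericMatrix out(rows, k * k * C);
  for (int ch = 0; ch < C; ++ch) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * ch;
        double* o = &out(0, q);
        const double* xi = &X(0, ch);
        // valid output rows i satisfy 0 <= i + di - pad < H
        const int i0 = std::max(0, pad - di);
        const int i1 = std::min(H - 1, H - 1 + pad - di);
        const int len = i1 - i0 + 1;
        for (int n = 0; n < N; ++n) {
          const long base = (long)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - pad;
            double* orow = o + base + (long)H * j;
            if (jj < 0 || jj >= W || len <= 0) {
              std::fill(orow, orow + H, 0.0);
              continue;
            }
            const double* irow = xi + base + (long)H * jj + (i0 + di - pad);
            if (i0 > 0) std::fill(orow, orow + i0, 0.0);
            std::memcpy(orow + i0, irow, sizeof(double) * len);
            if (i1 < H - 1) std::fill(orow + i1 + 1, orow + H, 0.0);
          }
        }
      }
    }
  }
  return out;
}

// Add a per-column bias in place (the matrix is freshly allocated by the
// caller and uniquely owned).
// [[Rcpp::export]]
void cpp_add_bias(NumericMatrix Z, const NumericVector& b) {
  const long n = Z.nrow();
  for (int c = 0; c < Z.ncol(); ++c) {
    double* z = &Z(0, c);
    const double bc = b[c];
    for (long i = 0; i < n; ++i) z[i] += bc;
  }
}

// Adjoint of im2col: scatter-add column gradients back to input layout.
// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& dcols, int H, int W, int N,
                         int k, int pad, int C) {
  const long HW = (long)H * W, rows = HW * N;
  NumericMatrix dX(rows, C);
  for (int ch = 0; ch < C; ++ch) {
    double* dx = &dX(0, ch);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int q = di + k * dj + k * k * ch;
        const double* d = &dcols(0, q);
        const int i0 = std::max(0, pad - di);
        const int i1 = std::min(H - 1, H - 1 + pad - di);
        if (i1 < i0) continue;
        for (int n = 0; n < N; ++n) {
          const long base = (long)n * HW;
          for (int j = 0; j < W; ++j) {
            const int jj = j + dj - pad;
            if (jj < 0 || jj >= W) continue;
            const double* drow = d + base + (long)H * j;
            double* xrow = dx + base + (long)H * jj + (di - pad);
            for (int i = i0; i <= i1; ++i) xrow[i] += drow[i];
          }
        }
      }
    }
  }
  return dX;
}

// 2x2 stride-2 max pooling with floor division (odd trailing row/col
// dropped). Returns the pooled matrix and 1-based source-row indices for the
// backward scatter.
// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& X, int H, int W, int N) {
  const int C = X.ncol();
  const int h2 = H / 2, w2 = W / 2;
  const long HW = (long)H * W, hw2 = (long)h2 * w2;
  NumericMatrix out(hw2 * N, C);
  IntegerMatrix idx(hw2 * N, C);
  for (int ch = 0; ch < C; ++ch) {
    const double* x = &X(0, ch);
    double* o = &out(0, ch);
    int* ix = &idx(0, ch);
    for (int n = 0; n < N; ++n) {
      const long base = (long)n * HW, obase = (long)n * hw2;
      for (int j = 0; j < w2; ++j) {
        for (int i = 0; i < h2; ++i) {
          long p00 = base + 2L * i + (long)H * (2L * j);
          long best = p00;
          double bv = x[p00];
          long cand[3] = {p00 + 1, p00 + H, p00 + H + 1};
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
          long orow = obase + i + (long)h2 * j;
          o[orow] = bv;
          ix[orow] = (int)(best + 1);  // 1-based within the column
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["h"] = h2, _["w"] = w2);
}
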