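#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Full Levenshtein DP, unit costs.
static int lev_full(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Levenshtein with early abandon: exact if <= limit, else limit + 1.
static int lev_bounded(const std::string& a, const std::string& b, int limit) {
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > limit) return limit + 1;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
      if (cur[j] < rowmin) rowmin = cur[j];
    }
    if (rowmin > limit) return limit + 1;
    std::swap(prev, cur);
  }
  return prev[m] > limit ? limit + 1 : prev[m];
}

// [[Rcpp::export]]
int cpp_lev(std::string a, std::string b) { return lev_full(a, b); }

// Distances from one query to many candidates. The abandon cap shrinks to
// (best distance so far + slack), so every value <= final min + slack is
// exact; larger entries are upper-bound sentinels (> cap at their time of
// evaluation). Callers use only the minimum and ties within `slack`.
// [[Rcpp::export]]
IntegerVector cpp_lev_scan(std::string q, CharacterVector cands,
                           int limit, int slack) {
  const int n = cands.size();
  IntegerVector out(n);
  int cap = limit;
  for (int i = 0; i < n; ++i) {
    std::string c = as<std::string>(cands[i]);
    int d = lev_bounded(q, c, cap);
    out[i] = d;
    if (d + slack < cap) cap = d + slack;
  }
  return out;
}

// Inverse-mapped bilinear warp. M maps output pixel coords (x, y, 1)
// (0-based, x = column, y = row) to source pixel coords. Samples outside
// the source get `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_warp(NumericMatrix src, NumericMatrix M,
                       int out_rows, int out_cols, double fill) {
  const int sr = src.nrow(), sc = src.ncol();
  NumericMatrix out(out_rows, out_cols);
  const double m00 = M(0, 0), m01 = M(0, 1), m02 = M(0, 2);
  const double m10 = M(1, 0), m11 = M(1, 1), m12 = M(1, 2);
  const double m20 = M(2, 0), m21 = M(2, 1), m22 = M(2, 2);
  for (int c = 0; c < out_cols; ++c) {
    for (int r = 0; r < out_rows; ++r) {
      double w = m20 * c + m21 * r + m22;
      double sx = (m00 * c + m01 * r + m02) / w;
      double sy = (m10 * c + m11 * r + m12) / w;
      int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
      double fx = sx - x0, fy = sy - y0;
      if (x0 < -1 || y0 < -1 || x0 > sc - 1 || y0 > sr - 1) {
        out(r, c) = fill;
        continue;
      }
      // clamp each corner to the image, use fill for truly outside corners
      double v00 = (x0 >= 0 && y0 >= 0) ? src(y0, x0) : fill;
      double v01 = (x0 + 1 < sc && y0 >= 0) ? src(y0, x0 + 1) : fill;
      double v10 = (x0 >= 0 && y0 + 1 < sr) ? src(y0 + 1, x0) : fill;
      double v11 = (x0 + 1 < sc && y0 + 1 < sr) ? src(y0 + 1, x0 + 1) : fill;
      out(r, c) = v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
                  v10 * (1 - fx) * fy + v11 * fx * fy;
    }
  }
  return out;
}

// Largest 8-connected component of a logical mask (TRUE = foreground).
// [[Rcpp::export]]
LogicalMatrix cpp_largest_component(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> label(nr * nc, 0);
  int best_label = 0, best_size = 0, next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int idx = i + j * nr;
      if (!mask(i, j) || label[idx]) continue;
      ++next;
      int size = 0;
      stack.clear();
      stack.push_back(idx);
      label[idx] = next;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        ++size;
        int ci = cur % nr, cj = cur / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            int nidx = ni + nj * nr;
            if (mask(ni, nj) && !label[nidx]) {
              label[nidx] = next;
              stack.push_back(nidx);
            }
          }
        }
      }
      if (size > best_size) { best_size = size; best_label = next; }
    }
  }
  LogicalMatrix out(nr, nc);
  if (best_label == 0) return out;  // empty mask: no component
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = (label[i + j * nr] == best_label);
  return out;
}
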