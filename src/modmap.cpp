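#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of a logical matrix. connectivity is 4 or 8.
// Background (FALSE/NA) gets label 0; components are numbered from 1 in
// scan order of their first pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  stack.reserve(256);
  int next = 0;

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) != TRUE || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * h);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % h, cj = idx / h;
        for (int k = 0; k < nn; ++k) {
          int ni = ci + dr[k], nj = cj + dc[k];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          if (mask(ni, nj) == TRUE && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * h);
          }
        }
      }
    }
  }
  return lab;
}

static double vec_median(std::vector<double> &v) {
  size_t m = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + m, v.end());
  double hi = v[m];
  if (v.size() % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + m - 1, v.begin() + m);
  return 0.5 * (hi + v[m - 1]);
}

// Medians of the truncated (shrinking) edge windows of a running median
// with half-width `half`: left[i] = median(x[0..i+half]) for i = 0..half-1,
// right[i] = median(x[(n-1-i-half)..(n-1)]) for i = 0..half-1.
// [[Rcpp::export(name = ".edge_medians")]]
List edge_medians(NumericVector x, int half) {
  const int n = x.size();
  const int m = std::min(half, n);
  NumericVector left(m), right(m);
  std::vector<double> buf;
  for (int i = 0; i < m; ++i) {
    int hi = std::min(n, i + half + 1);
    buf.assign(x.begin(), x.begin() + hi);
    left[i] = vec_median(buf);
    int lo = std::max(0, n - 1 - i - half);
    buf.assign(x.begin() + lo, x.end());
    right[i] = vec_median(buf);
  }
  return List::create(_["left"] = left, _["right"] = right);
}

// Grey-scale dilation (moving maximum) over a disk of the given pixel
// radius. NA cells are ignored as neighbours; an all-NA neighbourhood
// yields NA.
// [[Rcpp::export(name = ".max_filter_disk")]]
NumericMatrix max_filter_disk(NumericMatrix x, int radius) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix out(h, w);
  const int r2 = radius * radius;

  // precompute disk offsets
  std::vector<int> off_i, off_j;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= r2) {
        off_i.push_back(di);
        off_j.push_back(dj);
      }

  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double m = R_NegInf;
      bool any = false;
      for (size_t k = 0; k < off_i.size(); ++k) {
        int ni = i + off_i[k], nj = j + off_j[k];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        double v = x(ni, nj);
        if (NumericMatrix::is_na(v)) continue;
        any = true;
        if (v > m) m = v;
      }
      out(i, j) = any ? m : NA_REAL;
    }
  }
  return out;
}
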