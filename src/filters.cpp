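#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Symmetric (half-sample) boundary reflection shared by all windowed filters.
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

static inline double median_of(std::vector<double> &v) {
  std::sort(v.begin(), v.end());
  size_t m = v.size() / 2;
  if (v.size() % 2 == 1) return v[m];
  return 0.5 * (v[m - 1] + v[m]);
}

// Local mean and sample variance over a w x w window (w odd).
// [[Rcpp::export]]
List local_mean_var(NumericMatrix g, int w) {
  int nr = g.nrow(), nc = g.ncol(), r = w / 2, N = w * w;
  NumericMatrix mn(nr, nc), vr(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int dj = -r; dj <= r; ++dj) {
        int cj = reflect(j + dj, nc);
        for (int di = -r; di <= r; ++di) {
          double x = g(reflect(i + di, nr), cj);
          s += x; s2 += x * x;
        }
      }
      double m = s / N;
      double v = (s2 - N * m * m) / (N - 1);
      mn(i, j) = m;
      vr(i, j) = v > 0.0 ? v : 0.0;
    }
  }
  return List::create(_["mean"] = mn, _["var"] = vr);
}

// Plain w x w median filter.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix g, int w) {
  int nr = g.nrow(), nc = g.ncol(), r = w / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(w * w);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = -r; dj <= r; ++dj) {
        int cj = reflect(j + dj, nc);
        for (int di = -r; di <= r; ++di)
          buf.push_back(g(reflect(i + di, nr), cj));
      }
      out(i, j) = median_of(buf);
    }
  }
  return out;
}

// Hybrid median over a 5x5 neighbourhood: mean of the medians over the
// "+" cross, the "x" diagonal cross, and the full square.
// [[Rcpp::export]]
NumericMatrix hybrid_median_cpp(NumericMatrix g) {
  int nr = g.nrow(), nc = g.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> plus, cross, full;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      plus.clear(); cross.clear(); full.clear();
      for (int d = -2; d <= 2; ++d) {
        plus.push_back(g(reflect(i + d, nr), j));
        if (d != 0) plus.push_back(g(i, reflect(j + d, nc)));
        cross.push_back(g(reflect(i + d, nr), reflect(j + d, nc)));
        if (d != 0) cross.push_back(g(reflect(i + d, nr), reflect(j - d, nc)));
      }
      for (int dj = -2; dj <= 2; ++dj) {
        int cj = reflect(j + dj, nc);
        for (int di = -2; di <= 2; ++di)
          full.push_back(g(reflect(i + di, nr), cj));
      }
      out(i, j) = (median_of(plus) + median_of(cross) + median_of(full)) / 3.0;
    }
  }
  return out;
}

// Kuwahara-style 1D homogeneous-mask filter: among the four 1x5 segments
// through the pixel (horizontal, vertical, two diagonals), replace the pixel
// with the median of the minimum-variance segment.  Ties keep the first
// orientation in that fixed order.
// [[Rcpp::export]]
NumericMatrix kuwahara_cpp(NumericMatrix g) {
  int nr = g.nrow(), nc = g.ncol();
  NumericMatrix out(nr, nc);
  const int dirs[4][2] = {{0, 1}, {1, 0}, {1, 1}, {1, -1}}; // h, v, d1, d2
  std::vector<double> seg(5);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best_var = R_PosInf, best_med = g(i, j);
      for (int o = 0; o < 4; ++o) {
        double s = 0.0, s2 = 0.0;
        for (int d = -2; d <= 2; ++d) {
          double x = g(reflect(i + d * dirs[o][0], nr), reflect(j + d * dirs[o][1], nc));
          seg[d + 2] = x; s += x; s2 += x * x;
        }
        double m = s / 5.0, v = (s2 - 5.0 * m * m) / 4.0;
        if (v < 0.0) v = 0.0;
        if (v < best_var) {
          best_var = v;
          std::vector<double> tmp(seg);
          best_med = median_of(tmp);
        }
      }
      out(i, j) = best_med;
    }
  }
  return out;
}

// Minimum-speckle-index filter: over the nine 3x3 subwindows of the 5x5
// neighbourhood, the speckle index C = var/mean is computed on the
// log-compressed raster `lg`; the pixel is replaced by the subwindow mean of
// `g` (original domain) with the smallest C.  Subwindows with nonpositive
// log-domain mean are skipped; ties keep the earliest subwindow in row-major
// scan order of the (row offset, column offset) grid.
// [[Rcpp::export]]
NumericMatrix lsminsc_cpp(NumericMatrix g, NumericMatrix lg) {
  int nr = g.nrow(), nc = g.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double best_c = R_PosInf, best_mean = g(i, j);
      bool found = false;
      for (int oi = -1; oi <= 1; ++oi) {
        for (int oj = -1; oj <= 1; ++oj) {
          double s = 0.0, s2 = 0.0, sg = 0.0;
          for (int di = -1; di <= 1; ++di) {
            for (int dj = -1; dj <= 1; ++dj) {
              int ri = reflect(i + oi + di, nr), cj = reflect(j + oj + dj, nc);
              double x = lg(ri, cj);
              s += x; s2 += x * x;
              sg += g(ri, cj);
            }
          }
          double m = s / 9.0;
          if (m <= 0.0) continue;
          double v = (s2 - 9.0 * m * m) / 8.0;
          if (v < 0.0) v = 0.0;
          double c = v / m;
          if (c < best_c) { best_c = c; best_mean = sg / 9.0; found = true; }
        }
      }
      out(i, j) = found ? best_mean : g(i, j);
    }
  }
  return out;
}
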