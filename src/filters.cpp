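#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// reflect (symmetric, edge-repeating) index into [0, n)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Sliding-window rank-order filter. Each output pixel is the `rank`-th
// smallest (1-based) value in its window x window neighbourhood, with
// symmetric border reflection so the output has the input's size.
// [[Rcpp::export(name = ".rank_filter_cpp")]]
NumericMatrix rank_filter_cpp(NumericMatrix x, int rank, int window) {
  const int h = x.nrow(), w = x.ncol();
  const int half = window / 2, wsz = window * window;
  if (window < 1 || window % 2 == 0) stop("window must be odd and positive");
  if (rank < 1 || rank > wsz) stop("rank must lie in [1, window^2]");
  NumericMatrix out(h, w);
  std::vector<double> buf(wsz);
  const double *xp = x.begin();
  for (int j = 0; j < w; ++j) {
    const bool jEdge = (j < half) || (j >= w - half);
    for (int i = 0; i < h; ++i) {
      int n = 0;
      if (!jEdge && i >= half && i < h - half) {
        // interior fast path: contiguous column strips, no reflection
        for (int dj = -half; dj <= half; ++dj) {
          const double *col = xp + (size_t)(j + dj) * h + (i - half);
          for (int di = 0; di < window; ++di) buf[n++] = col[di];
        }
      } else {
        for (int dj = -half; dj <= half; ++dj) {
          const int jj = reflect_idx(j + dj, w);
          for (int di = -half; di <= half; ++di) {
            const int ii = reflect_idx(i + di, h);
            buf[n++] = x(ii, jj);
          }
        }
      }
      if (wsz <= 25) {
        // insertion sort: cheaper than nth_element at these sizes
        for (int a = 1; a < wsz; ++a) {
          const double v = buf[a];
          int b = a - 1;
          while (b >= 0 && buf[b] > v) { buf[b + 1] = buf[b]; --b; }
          buf[b + 1] = v;
        }
      } else {
        std::nth_element(buf.begin(), buf.begin() + (rank - 1),
                         buf.begin() + wsz);
      }
      out(i, j) = buf[rank - 1];
    }
  }
  return out;
}

// Local Shannon entropy (bits) of the gray-level histogram in a
// window x window neighbourhood. `bins` holds integer levels in
// [0, levels); only pixels with mask == TRUE enter the histogram and
// only masked pixels receive an entropy value (others are set to 0).
// [[Rcpp::export(name = ".local_entropy_cpp")]]
NumericMatrix local_entropy_cpp(IntegerMatrix bins, LogicalMatrix mask,
                                int window, int levels) {
  const int h = bins.nrow(), w = bins.ncol();
  const int half = window / 2;
  if (window < 1 || window % 2 == 0) stop("window must be odd and positive");
  if (levels < 2) stop("levels must be >= 2");
  if (mask.nrow() != h || mask.ncol() != w) stop("mask dimensions differ from image");
  NumericMatrix out(h, w);
  // c * log2(c) lookup for counts up to window^2
  const int wsz = window * window;
  std::vector<double> clog(wsz + 1, 0.0);
  for (int c = 2; c <= wsz; ++c) clog[c] = c * std::log2((double) c);
  std::vector<int> hist(levels, 0);
  std::vector<int> touched;
  touched.reserve(wsz);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j)) continue;
      int n = 0;
      const int i0 = std::max(0, i - half), i1 = std::min(h - 1, i + half);
      const int j0 = std::max(0, j - half), j1 = std::min(w - 1, j + half);
      for (int jj = j0; jj <= j1; ++jj) {
        for (int ii = i0; ii <= i1; ++ii) {
          if (!mask(ii, jj)) continue;
          const int b = bins(ii, jj);
          if (b < 0 || b >= levels) stop("bin value outside [0, levels)");
          if (hist[b]++ == 0) touched.push_back(b);
          ++n;
        }
      }
      double s = 0.0;
      for (size_t t = 0; t < touched.size(); ++t) s += clog[hist[touched[t]]];
      double hval = (n > 0) ? std::log2((double) n) - s / n : 0.0;
      if (hval < 1e-12) hval = 0.0;   // clamp float residue on flat windows
      out(i, j) = hval;
      for (size_t t = 0; t < touched.size(); ++t) hist[touched[t]] = 0;
      touched.clear();
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask; labels 1..n in
// scan order of first encounter, 0 for background.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(j * h + i);
      lab(i, j) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pi = p % h, pj = p / h;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= h || jj < 0 || jj >= w) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(jj * h + ii);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Lloyd k-means iterations. `x` is n x p, `centers` k x p (initial).
// Assignment ties go to the lowest cluster index; a cluster that
// empties is re-seeded at the point farthest from its assigned
// centroid. Stops when no centroid moves more than `tol` (Euclidean)
// or after `maxIter` sweeps. Returns final centers, 1-based labels and
// the per-iteration within-cluster sum of squares.
// [[Rcpp::export(name = ".lloyd_kmeans_cpp")]]
List lloyd_kmeans_cpp(NumericMatrix x, NumericMatrix centers,
                      int maxIter, double tol) {
  const int n = x.nrow(), p = x.ncol(), k = centers.nrow();
  NumericMatrix cen(clone(centers));
  IntegerVector labels(n);
  std::vector<double> bestd(n);
  NumericVector objective(maxIter, NA_REAL);
  int iters = 0;
  for (int it = 0; it < maxIter; ++it) {
    // assignment
    for (int i = 0; i < n; ++i) {
      double bd = R_PosInf;
      int bl = 0;
      for (int c = 0; c < k; ++c) {
        double d = 0.0;
        for (int j = 0; j < p; ++j) {
          const double t = x(i, j) - cen(c, j);
          d += t * t;
        }
        if (d < bd) { bd = d; bl = c; }
      }
      labels[i] = bl;
      bestd[i] = bd;
    }
    // update
    NumericMatrix newCen(k, p);
    std::vector<int> counts(k, 0);
    for (int i = 0; i < n; ++i) {
      ++counts[labels[i]];
      for (int j = 0; j < p; ++j) newCen(labels[i], j) += x(i, j);
    }
    for (int c = 0; c < k; ++c) {
      if (counts[c] > 0) {
        for (int j = 0; j < p; ++j) newCen(c, j) /= counts[c];
      } else {
        int far = 0;
        double fd = -1.0;
        for (int i = 0; i < n; ++i)
          if (bestd[i] > fd) { fd = bestd[i]; far = i; }
        for (int j = 0; j < p; ++j) newCen(c, j) = x(far, j);
        labels[far] = c;
        bestd[far] = 0.0;
      }
    }
    // objective under the updated centers
    double obj = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < p; ++j) {
        const double t = x(i, j) - newCen(labels[i], j);
        obj += t * t;
      }
    }
    objective[it] = obj;
    double shift2 = 0.0;
    for (int c = 0; c < k; ++c) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) {
        const double t = newCen(c, j) - cen(c, j);
        s += t * t;
      }
      if (s > shift2) shift2 = s;
    }
    cen = newCen;
    iters = it + 1;
    if (std::sqrt(shift2) < tol) break;
  }
  // final assignment so labels are a fixed point of the returned centers
  for (int i = 0; i < n; ++i) {
    double bd = R_PosInf;
    int bl = 0;
    for (int c = 0; c < k; ++c) {
      double d = 0.0;
      for (int j = 0; j < p; ++j) {
        const double t = x(i, j) - cen(c, j);
        d += t * t;
      }
      if (d < bd) { bd = d; bl = c; }
    }
    labels[i] = bl + 1;
    bestd[i] = bd;
  }
  for (int c = 1; c <= k; ++c) {
    bool seen = false;
    for (int i = 0; i < n; ++i) if (labels[i] == c) { seen = true; break; }
    if (!seen) {
      int far = 0;
      double fd = -1.0;
      for (int i = 0; i < n; ++i)
        if (bestd[i] > fd) { fd = bestd[i]; far = i; }
      labels[far] = c;
      bestd[far] = 0.0;
    }
  }
  return List::create(_["centers"] = cen, _["labels"] = labels,
                      _["objective"] = objective[Rcpp::Range(0, iters - 1)]);
}
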