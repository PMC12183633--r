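#include <Rcpp.h>
#include <vector>
#include <numeric>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exact k-th nearest-neighbour Euclidean distance for every row of x,
// excluding the point itself. Points are sorted on the first coordinate and
// each query scans outward from its own rank, stopping a direction once the
// first-coordinate gap alone exceeds the current k-th-best distance — exact
// for any d, near O(N log N) in low dimension, and worst-case O(N^2 d).
// Exact (never approximate) so entropy estimates are stable across runs.
// [[Rcpp::export(name = ".knn_kth_dist")]]
NumericVector knn_kth_dist(NumericMatrix x, int k) {
  const int n = x.nrow();
  const int d = x.ncol();
  if (k < 1 || k >= n)
    stop("k must satisfy 1 <= k < nrow(x)");

  // row-major copy for contiguous row access
  std::vector<double> xs(static_cast<size_t>(n) * d);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < d; ++j)
      xs[static_cast<size_t>(i) * d + j] = x(i, j);

  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    const double xa = xs[static_cast<size_t>(a) * d];
    const double xb = xs[static_cast<size_t>(b) * d];
    return xa < xb || (xa == xb && a < b);
  });

  NumericVector out(n);
  std::vector<double> best(k); // max-heap of the k smallest squared distances
  for (int p = 0; p < n; ++p) {
    const int i = ord[p];
    const double *xi = &xs[static_cast<size_t>(i) * d];
    int filled = 0;

    auto consider = [&](int j) -> bool { // false => this direction exhausted
      const double *xj = &xs[static_cast<size_t>(j) * d];
      const double gap0 = xi[0] - xj[0];
      const double gap2 = gap0 * gap0;
      if (filled == k && gap2 >= best[0])
        return false; // sorted: every further point in this direction is worse
      double s = gap2;
      if (filled == k) {
        const double cap = best[0];
        for (int c = 1; c < d; ++c) {
          const double diff = xi[c] - xj[c];
          s += diff * diff;
          if (s >= cap) return true;
        }
        std::pop_heap(best.begin(), best.end());
        best[k - 1] = s;
        std::push_heap(best.begin(), best.end());
      } else {
        for (int c = 1; c < d; ++c) {
          const double diff = xi[c] - xj[c];
          s += diff * diff;
        }
        best[filled++] = s;
        if (filled == k)
          std::make_heap(best.begin(), best.end());
      }
      return true;
    };

    int lo = p - 1, hi = p + 1;
    bool lo_open = lo >= 0, hi_open = hi < n;
    while (lo_open || hi_open) {
      if (lo_open) {
        if (!consider(ord[lo])) lo_open = false;
        else lo_open = (--lo >= 0);
      }
      if (hi_open) {
        if (!consider(ord[hi])) hi_open = false;
        else hi_open = (++hi < n);
      }
    }
    out[i] = std::sqrt(best[0]);
  }
  return out;
}
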