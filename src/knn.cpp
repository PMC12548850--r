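#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact k-nearest-neighbour mean distance per point (query excluded from its
// own neighbourhood). Brute force for small N; uniform-grid hash with
// expanding Chebyshev-shell search for large N. The shell stop criterion is
// exact: after visiting all cells with |offset| <= r, any unvisited point is
// at Euclidean distance >= r*h from the query, so once the current k-th best
// distance is <= r*h the neighbourhood is final.
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  NumericVector out(n);
  if (n <= 1 || k < 1) return out;
  if (k > n - 1) k = n - 1;

  const double *X = pts.begin();
  const double *Y = X + n;
  const double *Z = Y + n;

  if (n <= 2000) {
    std::vector<double> d2(n);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        const double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
        d2[j] = dx * dx + dy * dy + dz * dz;
      }
      d2[i] = R_PosInf;
      // nth_element leaves the k smallest (unordered) in the first k slots
      std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::sqrt(d2[j]);
      out[i] = s / k;
    }
    return out;
  }

  double mn[3] = {R_PosInf, R_PosInf, R_PosInf};
  double mx[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    mn[0] = std::min(mn[0], X[i]); mx[0] = std::max(mx[0], X[i]);
    mn[1] = std::min(mn[1], Y[i]); mx[1] = std::max(mx[1], Y[i]);
    mn[2] = std::min(mn[2], Z[i]); mx[2] = std::max(mx[2], Z[i]);
  }
  const double ex = mx[0] - mn[0], ey = mx[1] - mn[1], ez = mx[2] - mn[2];
  const double diag = std::sqrt(ex * ex + ey * ey + ez * ez);
  if (diag <= 0.0) return out;  // all points coincide: all distances zero
  // cell size sized for surface-like clouds: a few points per occupied cell
  const double h = std::max(2.0 * diag / std::sqrt((double)n), 1e-9);

  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<int> ci(n), cj(n), ck(n);
  const long long P1 = 73856093LL, P2 = 19349663LL;
  for (int i = 0; i < n; ++i) {
    ci[i] = (int)std::floor((X[i] - mn[0]) / h);
    cj[i] = (int)std::floor((Y[i] - mn[1]) / h);
    ck[i] = (int)std::floor((Z[i] - mn[2]) / h);
    grid[ci[i] + P1 * cj[i] + P2 * ck[i]].push_back(i);
  }
  const int rmax = (int)std::ceil(diag / h) + 1;

  std::vector<double> heap;  // max-heap of the k best squared distances
  heap.reserve(k + 1);
  for (int i = 0; i < n; ++i) {
    heap.clear();
    for (int r = 0; r <= rmax; ++r) {
      for (int dz = -r; dz <= r; ++dz) {
        for (int dy = -r; dy <= r; ++dy) {
          for (int dx = -r; dx <= r; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != r)
              continue;  // only the new shell
            auto it = grid.find((long long)(ci[i] + dx) + P1 * (cj[i] + dy) + P2 * (ck[i] + dz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (j == i) continue;
              const double ddx = X[i] - X[j], ddy = Y[i] - Y[j], ddz = Z[i] - Z[j];
              const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if ((int)heap.size() < k) {
                heap.push_back(d2);
                std::push_heap(heap.begin(), heap.end());
              } else if (d2 < heap.front()) {
                std::pop_heap(heap.begin(), heap.end());
                heap.back() = d2;
                std::push_heap(heap.begin(), heap.end());
              }
            }
          }
        }
      }
      if ((int)heap.size() >= k) {
        const double bound = (double)r * h;
        if (heap.front() <= bound * bound) break;
      }
    }
    double s = 0.0;
    for (double d2 : heap) s += std::sqrt(d2);
    out[i] = s / k;
  }
  return out;
}
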