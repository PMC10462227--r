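#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Brute-force exact k-nearest-neighbour search (Euclidean), self included as
// the first neighbour. Ties are broken by (distance, index) so the result is
// fully deterministic. Returns an n x (k+1) matrix of 1-based indices.
// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericMatrix x, int k) {
  const int n = x.nrow(), d = x.ncol();
  if (k + 1 > n) stop("fewer cells than k_neighbors");
  IntegerMatrix out(n, k + 1);
  std::vector<double> sq(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += x(i, j) * x(i, j);
    sq[i] = s;
  }
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double dot = 0.0;
      for (int c = 0; c < d; ++c) dot += x(i, c) * x(j, c);
      double dist = sq[i] + sq[j] - 2.0 * dot;
      cand[j] = std::make_pair(j == i ? -1.0 : dist, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k + 1, cand.end());
    for (int j = 0; j <= k; ++j) out(i, j) = cand[j].second + 1;
  }
  return out;
}
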