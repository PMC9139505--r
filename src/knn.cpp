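#include <Rcpp.h>
using namespace Rcpp;

// Brute-force k-nearest-neighbour indices for 2-D points.
// Returns an n x k matrix of 1-based neighbour indices, nearest first;
// ties broken toward the lower index (stable across platforms).
// [[Rcpp::export(name = ".knn_brute")]]
IntegerMatrix knn_brute(NumericMatrix x, int k) {
  const int n = x.nrow();
  if (k >= n) stop("k must be < number of points");
  IntegerMatrix out(n, k);
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  const double *px = &x(0, 0);
  const double *py = &x(0, 1);
  for (int i = 0; i < n; ++i) {
    int filled = 0;
    const double xi = px[i], yi = py[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = px[j] - xi, dy = py[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (filled == k && d2 >= bd[k - 1]) continue;
      // insertion into the sorted buffer of the k best so far
      int pos = (filled < k ? filled : k - 1);
      while (pos > 0 && bd[pos - 1] > d2) {
        bd[pos] = bd[pos - 1];
        bi[pos] = bi[pos - 1];
        --pos;
      }
      bd[pos] = d2;
      bi[pos] = j;
      if (filled < k) ++filled;
    }
    for (int j = 0; j < k; ++j) out(i, j) = bi[j] + 1;
  }
  return out;
}

// Distance from each source point to its nearest target point,
// excluding the same-index self match when same_set is true.
// [[Rcpp::export(name = ".nn_min_dist_cpp")]]
NumericVector nn_min_dist_cpp(NumericMatrix src, NumericMatrix tgt,
                              bool same_set) {
  const int ns = src.nrow(), nt = tgt.nrow();
  NumericVector out(ns);
  for (int i = 0; i < ns; ++i) {
    double best = R_PosInf;
    const double xi = src(i, 0), yi = src(i, 1);
    for (int j = 0; j < nt; ++j) {
      if (same_set && j == i) continue;
      const double dx = tgt(j, 0) - xi, dy = tgt(j, 1) - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
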