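#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Neighbour counts for the Kraskov-Stoegbauer-Grassberger algorithm-2
// mutual-information estimator.
//
// For each point i the k-th nearest neighbour is found under the max-norm
// in the joint (x, y) space; eps_x(i)/2 is the largest |x_i - x_j| over
// those k neighbours (analogously eps_y). n_x(i) counts the points j != i
// with |x_j - x_i| <= eps_x(i)/2 (closed ball, self excluded). Ties in the
// joint distance are assumed broken upstream by a small noise dither.
//
// [[Rcpp::export]]
IntegerMatrix ksg_counts_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  IntegerMatrix out(n, 2);
  std::vector<double> d(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = std::fabs(x[i] - x[j]);
      const double dy = std::fabs(y[i] - y[j]);
      d[j] = dx > dy ? dx : dy;
    }
    d[i] = R_PosInf;  // exclude self
    std::iota(idx.begin(), idx.end(), 0);
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&](int a, int b) { return d[a] < d[b]; });
    double ex = 0.0, ey = 0.0;
    for (int m = 0; m < k; ++m) {
      const int j = idx[m];
      ex = std::max(ex, std::fabs(x[i] - x[j]));
      ey = std::max(ey, std::fabs(y[i] - y[j]));
    }
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[j] - x[i]) <= ex) ++nx;
      if (std::fabs(y[j] - y[i]) <= ey) ++ny;
    }
    out(i, 0) = nx;
    out(i, 1) = ny;
  }
  return out;
}

// Full miR x mRNA grid of KSG algorithm-2 MI estimates (nats).
// `mir` and `mrna` are feature-by-sample matrices sharing the sample order;
// any tie-breaking noise must already be applied. Result: n_mir x n_mrna.
//
// [[Rcpp::export]]
NumericMatrix pairwise_ksg_cpp(NumericMatrix mir, NumericMatrix mrna, int k) {
  const int n = mir.ncol();
  if (mrna.ncol() != n) stop("matrices must share the sample dimension");
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n");
  const int nm = mir.nrow(), np = mrna.nrow();
  NumericMatrix out(nm, np);

  // digamma lookup for counts 1..n-1 (counts are at least k >= 1)
  std::vector<double> dg(n + 1);
  for (int v = 1; v <= n; ++v) dg[v] = R::digamma((double)v);
  const double base = R::digamma((double)k) - 1.0 / k + R::digamma((double)n);

  std::vector<double> adx(n * n), d(n);
  std::vector<int> idx(n);

  for (int a = 0; a < nm; ++a) {
    // per-sample |x_i - x_j| for this miR row, reused across all mRNA rows
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        adx[i * n + j] = std::fabs(mir(a, i) - mir(a, j));
    for (int b = 0; b < np; ++b) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        const double* dxi = &adx[i * n];
        for (int j = 0; j < n; ++j) {
          const double dy = std::fabs(mrna(b, i) - mrna(b, j));
          d[j] = dxi[j] > dy ? dxi[j] : dy;
        }
        d[i] = R_PosInf;
        std::iota(idx.begin(), idx.end(), 0);
        std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                          [&](int u, int v) { return d[u] < d[v]; });
        double ex = 0.0, ey = 0.0;
        for (int m = 0; m < k; ++m) {
          const int j = idx[m];
          ex = std::max(ex, dxi[j]);
          ey = std::max(ey, std::fabs(mrna(b, i) - mrna(b, j)));
        }
        int nx = 0, ny = 0;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          if (dxi[j] <= ex) ++nx;
          if (std::fabs(mrna(b, j) - mrna(b, i)) <= ey) ++ny;
        }
        acc += dg[nx] + dg[ny];
      }
      out(a, b) = base - acc / n;
    }
    if (a % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
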