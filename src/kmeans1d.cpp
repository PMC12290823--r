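#include <Rcpp.h>
#include <vector>
#include <cstdint>

// Exact weighted 1-D k-means by dynamic programming with the
// divide-and-conquer optimisation (the cost matrix satisfies the
// concave Monge condition, so optimal split points are monotone).
// Input: strictly increasing values x with positive weights w.
// Output: 1-based cluster id per value (ascending in x), centers, SSE.

namespace {

struct Prefix {
  std::vector<long double> W, WX, WXX;
  explicit Prefix(const Rcpp::NumericVector& x, const Rcpp::NumericVector& w)
      : W(x.size() + 1, 0.0L), WX(x.size() + 1, 0.0L), WXX(x.size() + 1, 0.0L) {
    for (int i = 0; i < x.size(); ++i) {
      W[i + 1] = W[i] + (long double)w[i];
      WX[i + 1] = WX[i] + (long double)w[i] * x[i];
      WXX[i + 1] = WXX[i] + (long double)w[i] * x[i] * x[i];
    }
  }
  // weighted SSE of points j..i (1-based, inclusive)
  long double cost(int j, int i) const {
    long double sw = W[i] - W[j - 1];
    if (sw <= 0.0L) return 0.0L;
    long double sx = WX[i] - WX[j - 1];
    long double sxx = WXX[i] - WXX[j - 1];
    long double c = sxx - sx * sx / sw;
    return c > 0.0L ? c : 0.0L;
  }
};

void solve_row(const Prefix& pre, const std::vector<long double>& prev,
               std::vector<long double>& cur, std::vector<int>& arg,
               int k, int lo, int hi, int optlo, int opthi) {
  if (lo > hi) return;
  int mid = (lo + hi) / 2;
  long double best = std::numeric_limits<long double>::infinity();
  int bestj = optlo;
  int jhi = std::min(mid, opthi);
  for (int j = std::max(k, optlo); j <= jhi; ++j) {
    long double v = prev[j - 1] + pre.cost(j, mid);
    if (v < best) {  // strict: ties keep the smallest split (lower cluster)
      best = v;
      bestj = j;
    }
  }
  cur[mid] = best;
  arg[mid] = bestj;
  solve_row(pre, prev, cur, arg, k, lo, mid - 1, optlo, bestj);
  solve_row(pre, prev, cur, arg, k, mid + 1, hi, bestj, opthi);
}

}  // namespace

// [[Rcpp::export(name = ".kmeans1d_dp")]]
Rcpp::List kmeans1d_dp(Rcpp::NumericVector x, Rcpp::NumericVector w, int K) {
  const int n = x.size();
  if (n == 0) Rcpp::stop("empty input");
  if (K < 1) Rcpp::stop("K must be >= 1");
  if (K > n) Rcpp::stop("K must not exceed the number of distinct values");
  for (int i = 1; i < n; ++i)
    if (!(x[i] > x[i - 1])) Rcpp::stop("values must be strictly increasing");

  Prefix pre(x, w);
  std::vector<long double> prev(n + 1), cur(n + 1);
  // arg[k][i]: first index of the k-th cluster in the optimal k-clustering
  // of points 1..i
  std::vector<std::vector<int>> args(K + 1, std::vector<int>(n + 1, 0));
  for (int i = 1; i <= n; ++i) {
    prev[i] = pre.cost(1, i);
    args[1][i] = 1;
  }
  for (int k = 2; k <= K; ++k) {
    std::vector<int> arg(n + 1, 0);
    solve_row(pre, prev, cur, arg, k, k, n, k, n);
    for (int i = 1; i < k; ++i) cur[i] = prev[i];  // unused region
    args[k] = arg;
    std::swap(prev, cur);
  }

  // backtrack cluster boundaries
  Rcpp::IntegerVector cluster(n);
  Rcpp::NumericVector centers(K), sizes(K);
  int i = n;
  for (int k = K; k >= 1; --k) {
    int j = (k == 1) ? 1 : args[k][i];
    long double sw = pre.W[i] - pre.W[j - 1];
    long double sx = pre.WX[i] - pre.WX[j - 1];
    centers[k - 1] = (double)(sx / sw);
    sizes[k - 1] = (double)sw;
    for (int t = j; t <= i; ++t) cluster[t - 1] = k;
    i = j - 1;
  }
  return Rcpp::List::create(Rcpp::Named("cluster") = cluster,
                            Rcpp::Named("centers") = centers,
                            Rcpp::Named("weights") = sizes,
                            Rcpp::Named("sse") = (double)prev[n]);
}
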