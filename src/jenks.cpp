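#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Fisher dynamic programme for natural-breaks classification:
// partition sorted values into k contiguous classes minimising the total
// within-class sum of squared deviations. O(k n^2) with prefix sums.
// Returns the 1-based start index of each class in the sorted vector.
// [[Rcpp::export(name = ".fisher_jenks_cpp")]]
IntegerVector fisher_jenks_cpp(NumericVector x_sorted, int k) {
  int n = x_sorted.size();
  if (k < 1 || n < k) stop("invalid k for Fisher-Jenks");
  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x_sorted[i];
    s2[i + 1] = s2[i] + x_sorted[i] * x_sorted[i];
  }
  // ssq of x[i..j] (0-based inclusive)
  auto ssq = [&](int i, int j) {
    double m = j - i + 1;
    double sum = s1[j + 1] - s1[i];
    return (s2[j + 1] - s2[i]) - sum * sum / m;
  };
  const double INF = std::numeric_limits<double>::infinity();
  // cost[c][j]: best total ssq of first j values split into c classes
  std::vector<std::vector<double>> cost(k + 1, std::vector<double>(n + 1, INF));
  std::vector<std::vector<int>> back(k + 1, std::vector<int>(n + 1, 0));
  cost[0][0] = 0.0;
  for (int c = 1; c <= k; ++c) {
    for (int j = c; j <= n; ++j) {
      // last class covers x[i..j-1], i ranges c-1 .. j-1
      for (int i = c - 1; i < j; ++i) {
        if (cost[c - 1][i] == INF) continue;
        double v = cost[c - 1][i] + ssq(i, j - 1);
        // strict < keeps the earliest feasible split -> deterministic ties
        if (v < cost[c][j]) { cost[c][j] = v; back[c][j] = i; }
      }
    }
  }
  IntegerVector starts(k);
  int j = n;
  for (int c = k; c >= 1; --c) {
    int i = back[c][j];
    starts[c - 1] = i + 1;  // 1-based start of class c
    j = i;
  }
  return starts;
}
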