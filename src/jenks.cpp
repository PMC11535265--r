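#include <Rcpp.h>
using namespace Rcpp;

// Exact Fisher-Jenks natural breaks on sorted data.
//
// Dynamic programme over contiguous partitions of the sorted values
// minimizing total within-class sum of squared deviations. E(i, c) is the
// minimal cost of partitioning values i..n into c classes; reconstruction
// scans forward choosing the smallest feasible class end at each level, so
// among cost-optimal partitions the one with lexicographically smallest
// break positions is returned.
//
// [[Rcpp::export]]
List jenks_dp(NumericVector x_sorted, int k) {
  const int n = x_sorted.size();
  if (k < 1 || k > n) stop("k must be between 1 and n");

  std::vector<double> s1(n + 1, 0.0), s2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    s1[i + 1] = s1[i] + x_sorted[i];
    s2[i + 1] = s2[i] + x_sorted[i] * x_sorted[i];
  }
  // within-class SSD of values i..j (1-based, inclusive)
  auto cost = [&](int i, int j) {
    double sum = s1[j] - s1[i - 1];
    double sq = s2[j] - s2[i - 1];
    int cnt = j - i + 1;
    double c = sq - sum * sum / cnt;
    return c > 0.0 ? c : 0.0;  // guard tiny negative rounding
  };

  // E[c][i]: min cost of partitioning i..n into c classes
  std::vector< std::vector<double> > E(k + 1,
      std::vector<double>(n + 2, R_PosInf));
  for (int i = 1; i <= n; ++i) E[1][i] = cost(i, n);
  for (int c = 2; c <= k; ++c) {
    for (int i = 1; i <= n - c + 1; ++i) {
      double best = R_PosInf;
      // first class is i..e; remaining c-1 classes need n-e >= c-1
      for (int e = i; e <= n - c + 1; ++e) {
        double v = cost(i, e) + E[c - 1][e + 1];
        if (v < best) best = v;
      }
      E[c][i] = best;
    }
  }

  const double total = E[k][1];
  // forward reconstruction: smallest class ends first
  IntegerVector ends(k);
  int s = 1;
  for (int c = k; c >= 2; --c) {
    double rem = E[c][s];
    double tol = 1e-10 * (std::fabs(rem) > 1.0 ? std::fabs(rem) : 1.0);
    for (int e = s; e <= n - c + 1; ++e) {
      if (cost(s, e) + E[c - 1][e + 1] <= rem + tol) {
        ends[k - c] = e;
        s = e + 1;
        break;
      }
    }
  }
  ends[k - 1] = n;

  return List::create(_["ssd"] = total, _["ends"] = ends);
}
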