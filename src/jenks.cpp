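// Fisher-Jenks optimal 1-D classification: dynamic programme minimising the
// total within-class sum of squared deviations over contiguous partitions of
// the sorted data. O(k n^2) with prefix sums.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// x must be sorted ascending. Returns 0-based index of the last element of
// each of the first k-1 classes, plus the achieved objective.
// [[Rcpp::export(name = ".jenks_cpp")]]
List jenks_cpp(NumericVector x, int k) {
  const int n = x.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  auto ssd = [&](int i, int j) { // inclusive 0-based range
    double s = cs[j + 1] - cs[i], s2 = cs2[j + 1] - cs2[i];
    int m = j - i + 1;
    return s2 - s * s / m;
  };
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<std::vector<double>> D(k + 1, std::vector<double>(n + 1, INF));
  std::vector<std::vector<int>> B(k + 1, std::vector<int>(n + 1, -1));
  D[0][0] = 0.0;
  for (int m = 1; m <= k; ++m) {
    for (int j = m; j <= n; ++j) {
      for (int i = m; i <= j; ++i) { // class m covers rows i..j (1-based)
        if (D[m - 1][i - 1] == INF) continue;
        double c = D[m - 1][i - 1] + ssd(i - 1, j - 1);
        if (c < D[m][j]) { D[m][j] = c; B[m][j] = i - 1; }
      }
    }
  }
  IntegerVector last(k);
  int j = n;
  for (int m = k; m >= 1; --m) {
    last[m - 1] = j - 1;
    j = B[m][j];
  }
  return List::create(_["last_index"] = last, _["objective"] = D[k][n]);
}
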