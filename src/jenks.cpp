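#include <Rcpp.h>
using namespace Rcpp;

// Fisher's optimal 1-D partition (Jenks natural breaks) by dynamic
// programming on the sorted values. O(k n^2) with prefix sums; returns
// 0-based index of the last element of each of the first k-1 classes.
// [[Rcpp::export(name = ".jenks_dp")]]
IntegerVector jenks_dp(NumericVector sorted_values, int k) {
  const int n = sorted_values.size();
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1]  = cs[i]  + sorted_values[i];
    cs2[i + 1] = cs2[i] + sorted_values[i] * sorted_values[i];
  }
  // ssq of values j..i inclusive (0-based)
  auto ssq = [&](int j, int i) {
    double s  = cs[i + 1] - cs[j];
    double s2 = cs2[i + 1] - cs2[j];
    int m = i - j + 1;
    return s2 - s * s / m;
  };
  // D[c][i]: min total ssq using c+1 classes for values 0..i
  std::vector<std::vector<double> > D(k, std::vector<double>(n, 0.0));
  std::vector<std::vector<int> > B(k, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) D[0][i] = ssq(0, i);
  for (int c = 1; c < k; ++c) {
    for (int i = c; i < n; ++i) {
      double best = R_PosInf; int arg = c;
      for (int j = c; j <= i; ++j) {
        double v = D[c - 1][j - 1] + ssq(j, i);
        if (v < best) { best = v; arg = j; }
      }
      D[c][i] = best;
      B[c][i] = arg;
    }
  }
  IntegerVector ends(k - 1);
  int i = n - 1;
  for (int c = k - 1; c >= 1; --c) {
    int j = B[c][i];       // first index of class c
    ends[c - 1] = j - 1;   // last index of class c-1
    i = j - 1;
  }
  return ends;
}
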