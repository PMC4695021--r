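#include <Rcpp.h>
using namespace Rcpp;

// Maximal circular-arc mean-shift statistic for CBS.
//
// For values x[1..n] consider every arc (i, j] of the circularized sequence
// (0 <= i < j <= n, excluding the full sequence) whose length k = j - i and
// complement length n - k are both >= min_width. The statistic is
//   T = |mean(arc) - mean(complement)| / sqrt(1/k + 1/(n-k)),
// i.e. a two-sample mean difference on the standard-error scale without a
// variance term (the overall variance is permutation-invariant, so omitting
// it does not change the permutation test). Returns the maximum T and its
// (i, j); ties keep the first (i, j) in scan order.
// [[Rcpp::export(name = ".cbs_max_stat")]]
List cbs_max_stat(NumericVector x, int min_width) {
  const int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double tot = S[n];

  double best = -1.0;
  int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i;
      if (k < min_width || n - k < min_width) continue;
      if (i == 0 && j == n) continue;
      const double arc = S[j] - S[i];
      const double diff = arc / k - (tot - arc) / (n - k);
      const double t = std::fabs(diff) / std::sqrt(1.0 / k + 1.0 / (n - k));
      if (t > best) {
        best = t;
        bi = i;
        bj = j;
      }
    }
  }
  return List::create(_["stat"] = best, _["i"] = bi, _["j"] = bj);
}

// Maximum statistic only (used inside the permutation loop).
// [[Rcpp::export(name = ".cbs_max_stat_only")]]
double cbs_max_stat_only(NumericVector x, int min_width) {
  const int n = x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double tot = S[n];

  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j <= n; ++j) {
      const int k = j - i;
      if (k < min_width || n - k < min_width) continue;
      if (i == 0 && j == n) continue;
      const double arc = S[j] - S[i];
      const double diff = arc / k - (tot - arc) / (n - k);
      const double t = std::fabs(diff) / std::sqrt(1.0 / k + 1.0 / (n - k));
      if (t > best) best = t;
    }
  }
  return best;
}
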