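#include <Rcpp.h>
using namespace Rcpp;

// Longest common subsequence between a performed and a target pitch sequence,
// returning the leftmost maximum-cardinality matching: each matched pair takes
// the earliest feasible performance index, then the earliest feasible target
// index. Indices in the returned two-column matrix are 1-based.
// [[Rcpp::export]]
IntegerMatrix lcs_match_cpp(IntegerVector perf, IntegerVector target) {
  const int n = perf.size(), m = target.size();
  // suffix DP: L[i][j] = LCS length of perf[i..n-1], target[j..m-1]
  std::vector<std::vector<int>> L(n + 1, std::vector<int>(m + 1, 0));
  for (int i = n - 1; i >= 0; --i)
    for (int j = m - 1; j >= 0; --j)
      L[i][j] = (perf[i] == target[j]) ? L[i + 1][j + 1] + 1
                                       : std::max(L[i + 1][j], L[i][j + 1]);
  int need = (n && m) ? L[0][0] : 0;
  IntegerMatrix pairs(need, 2);
  int i = 0, j = 0, k = 0;
  while (k < need) {
    // can performance index i be part of an optimal completion?
    int jj = -1;
    for (int t = j; t <= m - (need - k); ++t) {
      if (target[t] == perf[i] && 1 + L[i + 1][t + 1] >= need - k) { jj = t; break; }
    }
    if (jj >= 0) {
      pairs(k, 0) = i + 1;
      pairs(k, 1) = jj + 1;
      i += 1; j = jj + 1; k += 1;
    } else {
      i += 1;
    }
  }
  return pairs;
}

// Count rhythmically correct intervals among matched notes.
//
// pairs: 1-based (perf_index, target_index) rows, strictly increasing in both
// columns. onsets: performance onsets (seconds). cum_expected: nominal onset
// of each target note under the melody tempo (cumsum of expected IOIs, first
// element 0). tol: inclusive relative tolerance. first_mode: 0 = judge a
// first matched note at target index > 1 against the tempo grid,
// 1 = always count that judgment correct. A first matched note at target
// index 1 anchors the grid and is not judged.
// Returns c(n_judged, n_correct).
// [[Rcpp::export]]
IntegerVector rhythm_count_cpp(IntegerMatrix pairs, NumericVector onsets,
                               NumericVector cum_expected, double tol,
                               int first_mode) {
  // inclusive boundary with a relative guard against floating-point noise
  const double tol_eff = tol + 1e-9;
  int m = pairs.nrow();
  int judged = 0, correct = 0;
  if (m == 0) return IntegerVector::create(0, 0);
  int t1 = pairs(0, 1);
  if (t1 > 1) {
    judged += 1;
    if (first_mode == 1) {
      correct += 1;
    } else {
      double expected = cum_expected[t1 - 1];        // > 0 since t1 > 1
      double dev = std::fabs(onsets[pairs(0, 0) - 1] - expected) / expected;
      if (dev <= tol_eff) correct += 1;
    }
  }
  for (int k = 1; k < m; ++k) {
    double obs = onsets[pairs(k, 0) - 1] - onsets[pairs(k - 1, 0) - 1];
    double expd = cum_expected[pairs(k, 1) - 1] - cum_expected[pairs(k - 1, 1) - 1];
    judged += 1;
    if (expd > 0 && std::fabs(obs - expd) / expd <= tol_eff) correct += 1;
  }
  return IntegerVector::create(judged, correct);
}
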