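#include <Rcpp.h>
using namespace Rcpp;

// Pair-distance histograms over sorted, deduplicated read-start positions.
// Positions must be strictly increasing; lags are restricted to [0, W).
// A sliding right pointer gives O(N * k) where k is the mean number of
// positions within W of each start; no genome-length array is allocated.

// [[Rcpp::export(name = ".pair_lag_counts")]]
NumericVector pair_lag_counts(IntegerVector pos, int max_lag) {
  NumericVector counts(max_lag);
  R_xlen_t n = pos.size();
  // tau = 0: one self-pair per occupied position
  if (n > 0) counts[0] += (double)n;
  R_xlen_t j = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (j < i + 1) j = i + 1;
    while (j < n && (double)pos[j] - (double)pos[i] < (double)max_lag) ++j;
    for (R_xlen_t l = i + 1; l < j; ++l) {
      counts[pos[l] - pos[i]] += 1.0;
    }
  }
  return counts;
}

// Cross-strand histogram: ordered pairs (p, m) with m - p in [0, W).
// Both vectors sorted ascending.

// [[Rcpp::export(name = ".cross_lag_counts")]]
NumericVector cross_lag_counts(IntegerVector plus, IntegerVector minus,
                               int max_lag) {
  NumericVector counts(max_lag);
  R_xlen_t np = plus.size(), nm = minus.size();
  R_xlen_t lo = 0, hi = 0;
  for (R_xlen_t i = 0; i < np; ++i) {
    while (lo < nm && (double)minus[lo] < (double)plus[i]) ++lo;
    if (hi < lo) hi = lo;
    while (hi < nm && (double)minus[hi] - (double)plus[i] < (double)max_lag) ++hi;
    for (R_xlen_t l = lo; l < hi; ++l) {
      counts[minus[l] - plus[i]] += 1.0;
    }
  }
  return counts;
}
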