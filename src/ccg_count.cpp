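#include <Rcpp.h>
using namespace Rcpp;

// Lag histogram between two sorted spike-time vectors, restricted to pairs
// falling inside the same epoch. Lags are t_b - t_a, binned into
// floor((lag + max_lag) / bin_width) over [-max_lag, max_lag). Two-pointer
// sweep per epoch keeps this O(n + n_lags).
//
// a, b          sorted spike times (seconds), whole recording
// starts, ends  epoch bounds, half-open [start, end)
// bin_width     seconds
// n_bins        2 * max_lag / bin_width (max_lag = n_bins * bin_width / 2)
// [[Rcpp::export(name = ".ccg_count_cpp")]]
NumericVector ccg_count_cpp(NumericVector a, NumericVector b,
                            NumericVector starts, NumericVector ends,
                            double bin_width, int n_bins) {
  NumericVector counts(n_bins);
  const double max_lag = n_bins * bin_width / 2.0;
  const int na = a.size(), nb = b.size(), ne = starts.size();
  int ia0 = 0, ib0 = 0;
  for (int e = 0; e < ne; ++e) {
    const double s = starts[e], t = ends[e];
    while (ia0 < na && a[ia0] < s) ++ia0;
    while (ib0 < nb && b[ib0] < s) ++ib0;
    int ib_lo = ib0;
    for (int ia = ia0; ia < na && a[ia] < t; ++ia) {
      const double ta = a[ia];
      while (ib_lo < nb && b[ib_lo] < ta - max_lag && b[ib_lo] < t) ++ib_lo;
      for (int ib = (ib_lo > ib0 ? ib_lo : ib0); ib < nb && b[ib] < t; ++ib) {
        const double lag = b[ib] - ta;
        if (lag > max_lag) break;
        if (lag < -max_lag) continue;
        // closed interval [-max_lag, max_lag]: a lag of exactly +max_lag
        // falls in the last bin, keeping the histogram symmetric
        int k = (int)std::floor((lag + max_lag) / bin_width);
        if (k == n_bins) k = n_bins - 1;
        if (k >= 0 && k < n_bins) counts[k] += 1.0;
      }
    }
    // advance epoch cursors past this epoch (epochs are non-overlapping,
    // sorted); spikes between epochs are skipped by the < s test above
  }
  return counts;
}
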