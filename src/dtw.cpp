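#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Dynamic time warping, symmetric step pattern (diagonal, horizontal,
// vertical), |a_i - b_j| local cost, boundary-to-boundary alignment.
//
// The DP row for prefix a[1..i] already holds the optimal alignment of
// that prefix against all of b, so a single pass yields the whole
// incremental-window distance profile: out[i-1] = DTW(a[1..i], b).

// [[Rcpp::export(name = ".dtw_prefix_1d")]]
NumericVector dtw_prefix_1d(NumericVector a, NumericVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("dtw: empty sequence");
  std::vector<double> prev(m), cur(m);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double c = std::fabs(a[i] - b[j]);
      double best;
      if (i == 0 && j == 0)      best = 0.0;
      else if (i == 0)           best = cur[j - 1];
      else if (j == 0)           best = prev[0];
      else {
        best = prev[j - 1];
        if (prev[j] < best) best = prev[j];
        if (cur[j - 1] < best) best = cur[j - 1];
      }
      cur[j] = c + best;
    }
    out[i] = cur[m - 1];
    std::swap(prev, cur);
  }
  return out;
}

// [[Rcpp::export(name = ".dtw_cost_1d")]]
double dtw_cost_1d(NumericVector a, NumericVector b) {
  NumericVector p = dtw_prefix_1d(a, b);
  return p[p.size() - 1];
}
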