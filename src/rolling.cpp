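#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Centered rolling minimum with truncated edge windows.
// Window w covers indices [i - h_l, i + h_r] with h_l = (w-1)/2 (floor) and
// h_r = w - 1 - h_l, clipped to the vector; O(n) via a monotonic deque.
// [[Rcpp::export(name = ".roll_min_center")]]
NumericVector roll_min_center(NumericVector x, int window) {
  int n = x.size();
  if (window < 1) stop("window must be >= 1");
  NumericVector out(n);
  int h_l = (window - 1) / 2;
  int h_r = window - 1 - h_l;
  std::deque<int> q; // indices, values increasing
  int added = -1;
  for (int i = 0; i < n; ++i) {
    int hi = i + h_r;
    if (hi > n - 1) hi = n - 1;
    while (added < hi) {
      ++added;
      while (!q.empty() && x[q.back()] >= x[added]) q.pop_back();
      q.push_back(added);
    }
    int lo = i - h_l;
    while (!q.empty() && q.front() < lo) q.pop_front();
    out[i] = x[q.front()];
  }
  return out;
}

// Centered moving average with truncated edge windows (same window geometry
// as roll_min_center), computed from a running cumulative sum.
// [[Rcpp::export(name = ".roll_mean_center")]]
NumericVector roll_mean_center(NumericVector x, int window) {
  int n = x.size();
  if (window < 1) stop("window must be >= 1");
  NumericVector out(n);
  int h_l = (window - 1) / 2;
  int h_r = window - 1 - h_l;
  std::vector<long double> cs(n + 1, 0.0L);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + (long double)x[i];
  for (int i = 0; i < n; ++i) {
    int lo = i - h_l; if (lo < 0) lo = 0;
    int hi = i + h_r; if (hi > n - 1) hi = n - 1;
    out[i] = (double)((cs[hi + 1] - cs[lo]) / (hi - lo + 1));
  }
  return out;
}
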