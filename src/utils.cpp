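#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Trailing range (max - min) over a sliding window of w samples ending at
// each position; positions < w use the partial window. Monotonic-deque
// implementation, O(n).
// [[Rcpp::export]]
NumericVector cpp_trailing_range(NumericVector x, int w) {
  int n = x.size();
  NumericVector out(n);
  std::deque<int> qmax, qmin;
  for (int i = 0; i < n; ++i) {
    while (!qmax.empty() && x[qmax.back()] <= x[i]) qmax.pop_back();
    qmax.push_back(i);
    while (!qmin.empty() && x[qmin.back()] >= x[i]) qmin.pop_back();
    qmin.push_back(i);
    int lo = i - w + 1;
    if (qmax.front() < lo) qmax.pop_front();
    if (qmin.front() < lo) qmin.pop_front();
    out[i] = x[qmax.front()] - x[qmin.front()];
  }
  return out;
}

// Morphological dilation of a logical mask: every TRUE marks the preceding
// `left` and following `right` samples as well.
// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector x, int left, int right) {
  int n = x.size();
  LogicalVector out(n);
  int until = -1;
  for (int i = 0; i < n; ++i) {
    if (x[i]) {
      int from = i - left;
      if (from < 0) from = 0;
      if (from > until + 1) until = from - 1;
      int to = i + right;
      if (to >= n) to = n - 1;
      for (int j = (until + 1 > from ? until + 1 : from); j <= to; ++j)
        out[j] = true;
      if (to > until) until = to;
    }
  }
  return out;
}
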