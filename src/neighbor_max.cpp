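#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Sliding half-window maxima via monotonic deques, O(n).
// leftmax[i]  = max(x[i-h .. i-1]), -Inf when the half-window is empty;
// rightmax[i] = max(x[i+1 .. i+h]), -Inf when empty. 0-based internally,
// returned vectors align with x.
// [[Rcpp::export(name = ".neighborMax")]]
List neighbor_max(NumericVector x, int h) {
  const int n = x.size();
  if (h < 1) stop("half-window must be >= 1");
  NumericVector left(n), right(n);
  const double ninf = R_NegInf;

  std::deque<int> dq; // indices with decreasing x
  for (int i = 0; i < n; ++i) {
    // window for left[i] is [i-h, i-1]
    while (!dq.empty() && dq.front() < i - h) dq.pop_front();
    left[i] = dq.empty() ? ninf : x[dq.front()];
    while (!dq.empty() && x[dq.back()] <= x[i]) dq.pop_back();
    dq.push_back(i);
  }

  dq.clear();
  for (int i = n - 1; i >= 0; --i) {
    while (!dq.empty() && dq.front() > i + h) dq.pop_front();
    right[i] = dq.empty() ? ninf : x[dq.front()];
    while (!dq.empty() && x[dq.back()] <= x[i]) dq.pop_back();
    dq.push_back(i);
  }

  return List::create(_["left"] = left, _["right"] = right);
}
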