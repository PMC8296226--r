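#include <Rcpp.h>
using namespace Rcpp;

// Longest common subsequence length for two planar point sequences.
// Points i (of a) and j (of b) match when their planar Euclidean distance
// is <= eps and, if delta >= 0, |i - j| <= delta (indices on the shared
// 1 Hz grid, so the index offset is a time offset in samples). Standard
// O(n*m) dynamic programme over the (rolling) score matrix.
// [[Rcpp::export(name = ".lcss_length_cpp")]]
int lcss_length_cpp(NumericVector ax, NumericVector ay,
                    NumericVector bx, NumericVector by,
                    double eps, double delta) {
  const int n = ax.size(), m = bx.size();
  if (n == 0 || m == 0) return 0;
  const double eps2 = eps * eps;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      bool within_window = (delta < 0) || (std::abs(i - j) <= delta);
      if (within_window) {
        double dx = ax[i - 1] - bx[j - 1];
        double dy = ay[i - 1] - by[j - 1];
        if (dx * dx + dy * dy <= eps2) {
          cur[j] = prev[j - 1] + 1;
          if (prev[j] > cur[j]) cur[j] = prev[j];
          if (cur[j - 1] > cur[j]) cur[j] = cur[j - 1];
          continue;
        }
      }
      cur[j] = prev[j] > cur[j - 1] ? prev[j] : cur[j - 1];
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
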