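#include <Rcpp.h>
using namespace Rcpp;

// Discrete Frechet distance between two polylines given as n x 2 matrices.
// Standard dynamic program over monotone couplings, two-row rolling storage.
// [[Rcpp::export]]
double frechet_dp(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  if (n == 0 || m == 0) stop("empty curve");
  std::vector<double> prev(m), cur(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      const double dx = a(i, 0) - b(j, 0);
      const double dy = a(i, 1) - b(j, 1);
      const double d = std::sqrt(dx * dx + dy * dy);
      double reach;
      if (i == 0 && j == 0) {
        reach = d;
      } else if (i == 0) {
        reach = std::max(cur[j - 1], d);
      } else if (j == 0) {
        reach = std::max(prev[0], d);
      } else {
        const double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
        reach = std::max(best, d);
      }
      cur[j] = reach;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
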