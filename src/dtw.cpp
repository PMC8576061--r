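#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with absolute-difference local cost, symmetric2 step
// pattern (diagonal weighted twice), full window. Returns the accumulated
// cost; normalization by n + m happens on the R side.
// [[Rcpp::export(name = ".dtw_cost")]]
double dtw_cost(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n < 1 || m < 1) stop("empty series");
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      double c = std::fabs(x[i - 1] - y[j - 1]);
      double diag = prev[j - 1] + 2.0 * c;
      double up = prev[j] + c;
      double left = cur[j - 1] + c;
      cur[j] = std::min(diag, std::min(up, left));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
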