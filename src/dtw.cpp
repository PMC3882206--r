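#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with the symmetric step pattern
// (diagonal, vertical, horizontal) and squared-difference local cost.
// Returns the optimal cumulative cost and the optimal monotone path
// (1-based index pairs from (1,1) to (n,m)).
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n < 2 || m < 2) stop("curves need >= 2 points");
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 = diagonal, 1 = up (i-1), 2 = left (j-1)
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = (x[i] - y[j]) * (x[i] - y[j]);
      if (i == 0 && j == 0) {
        D(i, j) = c; from(i, j) = -1;
      } else if (i == 0) {
        D(i, j) = D(i, j - 1) + c; from(i, j) = 2;
      } else if (j == 0) {
        D(i, j) = D(i - 1, j) + c; from(i, j) = 1;
      } else {
        double diag = D(i - 1, j - 1), up = D(i - 1, j), left = D(i, j - 1);
        double best = diag; int arg = 0;
        if (up < best) { best = up; arg = 1; }
        if (left < best) { best = left; arg = 2; }
        D(i, j) = best + c; from(i, j) = arg;
      }
    }
  }
  // backtrack
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (i >= 0 && j >= 0) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    int f = from(i, j);
    if (f == -1) break;
    if (f == 0) { --i; --j; }
    else if (f == 1) --i;
    else --j;
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = D(n - 1, m - 1),
                      _["index_ref"] = wrap(pi),
                      _["index_query"] = wrap(pj));
}
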