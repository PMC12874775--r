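#include <Rcpp.h>
using namespace Rcpp;

// Pairwise tie-corrected Kendall tau-b with optional observation weights.
// Pair (i, j) contributes weight w_i * w_j; with unit weights the estimator
// reduces exactly to the classical tau-b.  Returns the weighted concordance
// sums needed by the R wrapper.
// [[Rcpp::export(name = ".kendall_pair_sums")]]
NumericVector kendall_pair_sums(NumericVector x, NumericVector y,
                                NumericVector w) {
  int n = x.size();
  double num = 0.0, W = 0.0, tx = 0.0, ty = 0.0, txy = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double ww = w[i] * w[j];
      double dx = x[i] - x[j], dy = y[i] - y[j];
      W += ww;
      bool ex = dx == 0.0, ey = dy == 0.0;
      if (ex && ey) { txy += ww; continue; }
      if (ex) { tx += ww; continue; }
      if (ey) { ty += ww; continue; }
      num += ((dx > 0) == (dy > 0)) ? ww : -ww;
    }
  }
  return NumericVector::create(_["num"] = num, _["W"] = W, _["tx"] = tx,
                               _["ty"] = ty, _["txy"] = txy);
}
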