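#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// SIMBA weight learning: iterate samples in the given order; for each,
// find the nearest hit and nearest miss in the w^2-scaled Euclidean metric
// and take a gradient-ascent step on the hypothesis margin (linear
// utility). The learning rate decays as lr / sqrt(t).
// [[Rcpp::export]]
NumericVector simba_weights(NumericMatrix X, IntegerVector y,
                            IntegerVector order, double lr) {
  int n = X.nrow(), p = X.ncol();
  NumericVector w(p, 1.0);
  std::vector<double> dh(p), dm(p);
  long t = 0;
  for (int oi = 0; oi < order.size(); ++oi) {
    int i = order[oi] - 1;  // 1-based from R
    double best_hit = R_PosInf, best_miss = R_PosInf;
    int ih = -1, im = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double d = 0.0;
      for (int k = 0; k < p; ++k) {
        double w2 = w[k] * w[k];
        double df = X(i, k) - X(j, k);
        d += w2 * df * df;
      }
      if (y[j] == y[i]) {
        if (d < best_hit) { best_hit = d; ih = j; }
      } else {
        if (d < best_miss) { best_miss = d; im = j; }
      }
    }
    if (ih < 0 || im < 0) continue;
    double dist_h = std::sqrt(best_hit), dist_m = std::sqrt(best_miss);
    if (dist_h < 1e-12) dist_h = 1e-12;
    if (dist_m < 1e-12) dist_m = 1e-12;
    ++t;
    double step = lr / std::sqrt((double)t);
    for (int k = 0; k < p; ++k) {
      double dfh = X(i, k) - X(ih, k);
      double dfm = X(i, k) - X(im, k);
      double grad = 0.5 * (dfm * dfm / dist_m - dfh * dfh / dist_h) * w[k];
      w[k] += step * grad;
    }
  }
  return w;
}
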