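#include <Rcpp.h>
using namespace Rcpp;

// First-return times for recurrence period density entropy.
// For each embedded point, the trajectory must first leave the eps-ball
// around it and then re-enter; the re-entry delay is the return time.
// [[Rcpp::export]]
IntegerVector rpde_return_times(NumericVector x, int m, int tau, double eps,
                                int t_max) {
  int n = x.size() - (m - 1) * tau;
  if (n <= 1) return IntegerVector(0);
  std::vector<int> times;
  double eps2 = eps * eps;
  for (int i = 0; i < n - 1; ++i) {
    bool left = false;
    int limit = std::min(n - 1, i + t_max);
    for (int j = i + 1; j <= limit; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = x[j + k * tau] - x[i + k * tau];
        d2 += d * d;
        if (d2 > eps2 && left) break;  // early exit only useful post-exit
      }
      if (!left) {
        if (d2 > eps2) left = true;
      } else if (d2 <= eps2) {
        times.push_back(j - i);
        break;
      }
    }
  }
  return wrap(times);
}
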