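#include <Rcpp.h>
using namespace Rcpp;

// Two-sided CUSUM change-point segmentation for mean shifts in Gaussian
// noise. The reference level is the running mean of the current segment;
// the cumulative statistics accumulate standardized deviations minus the
// allowance k = delta/(2*sigma); an alarm fires when either statistic
// exceeds h (in sigma units), and the change point is placed at the last
// index where that statistic was zero. Segmentation restarts after each
// detected change.
//
// Returns 1-based indices of the last sample of each segment except the
// final one (i.e. change points c: segments are [..c], [c+1..]).
// [[Rcpp::export]]
IntegerVector cusum_changepoints(NumericVector x, double sigma, double k,
                                 double h) {
  int n = x.size();
  std::vector<int> cps;
  if (n < 2 || sigma <= 0) return IntegerVector(0);
  int seg_start = 0;
  while (seg_start < n - 1) {
    double mean = 0.0;
    int m = 0;
    double sp = 0.0, sm = 0.0;
    int lzp = seg_start, lzm = seg_start; // last zero of each statistic
    int alarm = -1, cp = -1;
    for (int i = seg_start; i < n; ++i) {
      double z = 0.0;
      if (m > 0) z = (x[i] - mean) / sigma; // deviation from past mean
      ++m;
      mean += (x[i] - mean) / m;
      sp += z - k; if (sp < 0) { sp = 0; lzp = i; }
      sm += -z - k; if (sm < 0) { sm = 0; lzm = i; }
      if (sp > h || sm > h) {
        alarm = i;
        cp = (sp > h) ? lzp : lzm;
        break;
      }
    }
    if (alarm < 0) break;       // no further change in this window
    if (cp < seg_start) cp = seg_start;
    if (cp >= n - 1) break;
    cps.push_back(cp + 1);      // 1-based last index of left segment
    seg_start = cp + 1;
  }
  return wrap(cps);
}
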