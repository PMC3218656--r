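#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Maximal standardized mean-difference statistic over circular arcs
// (i, j] of x (0-based boundaries, arc = indices i..j-1, complement the
// rest). Width constraints: arc and complement >= minw, and any piece a
// split would create (prefix before i, suffix after j) >= minw.
static void max_stat(const std::vector<double>& x, int minw, double& best,
                     int& bi, int& bj) {
  int n = (int)x.size();
  std::vector<double> cs(n + 1, 0.0);
  double tot = 0.0, tot2 = 0.0;
  for (int k = 0; k < n; ++k) {
    cs[k + 1] = cs[k] + x[k];
    tot += x[k];
    tot2 += x[k] * x[k];
  }
  double mean = tot / n;
  double var = tot2 / n - mean * mean;
  best = 0.0; bi = -1; bj = -1;
  if (var < 1e-14) return;  // constant signal: no split
  double sd = std::sqrt(var * (double)n / (double)(n - 1));
  for (int i = 0; i <= n - 1; ++i) {
    if (i > 0 && i < minw) continue;
    for (int j = i + 1; j <= n; ++j) {
      int nin = j - i, nout = n - nin;
      if (nout == 0 || nin < minw || nout < minw) continue;
      if (j < n && n - j < minw) continue;
      double a_in = (cs[j] - cs[i]) / nin;
      double a_out = (tot - (cs[j] - cs[i])) / nout;
      double t = std::fabs(a_in - a_out) /
                 (sd * std::sqrt(1.0 / nin + 1.0 / nout));
      if (t > best) { best = t; bi = i; bj = j; }
    }
  }
}

// Best split of a segment with its permutation p-value. Permutations use
// R's RNG (deterministic under set.seed). Permutation stops early once the
// exceedance count proves p > alpha.
// [[Rcpp::export]]
List cbs_best_split(NumericVector xr, int minw, int nperm, double alpha) {
  std::vector<double> x(xr.begin(), xr.end());
  double obs; int bi, bj;
  max_stat(x, minw, obs, bi, bj);
  if (bi < 0 || obs <= 0.0)
    return List::create(_["i"] = -1, _["j"] = -1, _["p"] = 1.0,
                        _["stat"] = 0.0);
  int n = (int)x.size();
  std::vector<double> y(x);
  int exceed = 0, done = 0;
  int limit = (int)std::floor(alpha * nperm);
  for (int p = 0; p < nperm; ++p) {
    for (int k = n - 1; k > 0; --k) {
      int idx = (int)(unif_rand() * (k + 1));
      if (idx > k) idx = k;
      std::swap(y[k], y[idx]);
    }
    double b; int i2, j2;
    max_stat(y, minw, b, i2, j2);
    ++done;
    if (b >= obs) ++exceed;
    if (exceed > limit) break;
  }
  double pval = (exceed > limit) ? 1.0 : (exceed + 1.0) / (done + 1.0);
  return List::create(_["i"] = bi, _["j"] = bj, _["p"] = pval,
                      _["stat"] = obs);
}
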