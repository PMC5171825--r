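#include <Rcpp.h>
using namespace Rcpp;

// Maximal circular-arc t^2 statistic.
//
// For a segment x[0..n-1] viewed as a circle, every split into two arcs is
// indexed by a contiguous window (i, j] of width w = j - i (its complement is
// the wrapping arc).  With prefix sums S, pooled variance held fixed at the
// segment variance (permutation-invariant), the two-sample t^2 for the window
// against its complement reduces to
//   t^2(i, j) = n * (S[j] - S[i] - w * mu)^2 / (w * (n - w) * sigma2).
// Enumerating w in [min_width, n/2] covers every split once.
static double max_arc_t2(const double *S, int n, double mu, double sigma2,
                         int min_width, int *bi, int *bj, double stop_above) {
  double best = -1.0;
  int wmax = n / 2;
  if (wmax < min_width) return 0.0;
  for (int w = min_width; w <= wmax; ++w) {
    if (n - w < min_width) continue;
    double c = (double)n / ((double)w * (double)(n - w) * sigma2);
    double off = w * mu;
    double thr = (stop_above > 0.0) ? stop_above / c : -1.0; // compare v^2
    double vbest = -1.0;
    int ibest = -1;
    for (int i = 0; i + w <= n; ++i) {
      double v = S[i + w] - S[i] - off;
      double v2 = v * v;
      if (v2 > vbest) { vbest = v2; ibest = i; }
      if (thr > 0.0 && v2 > thr) { // early exit: exceedance established
        if (bi) { *bi = ibest; *bj = ibest + w; }
        return v2 * c;
      }
    }
    double t2 = vbest * c;
    if (t2 > best) {
      best = t2;
      if (bi) { *bi = ibest; *bj = ibest + w; }
    }
  }
  return best;
}

// Permutation-mode scan: does any arc reach t2 >= t2_obs?  Avoids argmax
// bookkeeping so the inner loop stays a two-flop compare.
static bool any_arc_exceeds(const double *S, int n, double mu, double sigma2,
                            int min_width, double t2_obs) {
  int wmax = n / 2;
  for (int w = min_width; w <= wmax; ++w) {
    if (n - w < min_width) continue;
    double thr = t2_obs * (double)w * (double)(n - w) * sigma2 / (double)n;
    double off = w * mu;
    int m = n - w;
    for (int i = 0; i <= m; ++i) {
      double v = S[i + w] - S[i] - off;
      if (v * v >= thr) return true;
    }
  }
  return false;
}

// Test the best circular split of x by permutation.
//
// Returns the observed statistic, the arc bounds (0-based, arc = x[i..j-1]),
// the permutation p-value and the number of permutations actually run.
// Permutations stop early once the exceedance count already implies
// p >= alpha (the decision cannot change); the reported p is then a lower
// bound flagged by early_stop.  Uses R's RNG, so results are reproducible
// under set.seed().
// [[Rcpp::export(name = ".cbs_test_split")]]
List cbs_test_split(NumericVector x, int min_width, double alpha, int nperm) {
  int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["t2"] = 0.0, _["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["p"] = 1.0, _["nperm_done"] = 0, _["early_stop"] = false);
  std::vector<double> S(n + 1, 0.0);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { tot += x[i]; S[i + 1] = tot; }
  double mu = tot / n;
  double ss = 0.0;
  for (int i = 0; i < n; ++i) { double d = x[i] - mu; ss += d * d; }
  double sigma2 = ss / (n - 1);
  if (sigma2 <= 0.0)
    return List::create(_["t2"] = 0.0, _["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["p"] = 1.0, _["nperm_done"] = 0, _["early_stop"] = false);

  int bi = -1, bj = -1;
  double t2_obs = max_arc_t2(S.data(), n, mu, sigma2, min_width, &bi, &bj, -1.0);

  int kstop = (int)std::ceil(alpha * nperm); // exceedances implying p >= alpha
  if (kstop < 1) kstop = 1;
  std::vector<double> xp(x.begin(), x.end());
  std::vector<double> Sp(n + 1, 0.0);
  int exceed = 0, done = 0;
  bool early = false;
  for (int b = 0; b < nperm; ++b) {
    // Fisher-Yates with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int k = (int)(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(xp[i], xp[k]);
    }
    double t = 0.0;
    for (int i = 0; i < n; ++i) { t += xp[i]; Sp[i + 1] = t; }
    if (any_arc_exceeds(Sp.data(), n, mu, sigma2, min_width, t2_obs)) ++exceed;
    ++done;
    if (exceed >= kstop) { early = true; break; }
  }
  double p = early ? alpha : (double)exceed / (double)nperm;
  return List::create(_["t2"] = t2_obs, _["i"] = bi, _["j"] = bj,
                      _["p"] = p, _["nperm_done"] = done,
                      _["early_stop"] = early);
}
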