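#include <Rcpp.h>
using namespace Rcpp;

// Artificially-centered hit-and-run over the polytope
//   { x : A x = 0 (via projector), lb <= x <= ub }.
//
// Directions are differences between a randomly chosen warmup point and
// the running center of all points generated so far, projected onto the
// null space of the equality constraints (matrix `proj`, which also
// encodes coordinates pinned by equal bounds). Uses R's RNG so results
// are reproducible under set.seed().
//
// [[Rcpp::export]]
NumericMatrix achr_core(NumericMatrix warmup, NumericVector x0,
                        NumericMatrix proj, NumericVector lb,
                        NumericVector ub, int n_samples, int thinning,
                        int burn, double dir_tol) {
  const int n = x0.size();
  const int k = warmup.nrow();
  NumericMatrix out(n_samples, n);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> center(n, 0.0);

  // initial center: mean of warmup points
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int i = 0; i < k; ++i) s += warmup(i, j);
    center[j] = s / k;
  }
  double cnt = (double)k;

  std::vector<double> d0(n), d(n);
  long total = (long)burn + (long)n_samples * thinning;
  int recorded = 0, since = 0;

  for (long step = 0; step < total; ++step) {
    int r = (int)(unif_rand() * k);
    if (r >= k) r = k - 1;
    for (int j = 0; j < n; ++j) d0[j] = warmup(r, j) - center[j];
    // project onto the feasible direction space
    double nrm = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += proj(i, j) * d0[j];
      d[i] = s;
      nrm += s * s;
    }
    nrm = std::sqrt(nrm);
    bool moved = false;
    if (nrm > dir_tol) {
      for (int i = 0; i < n; ++i) d[i] /= nrm;
      double tmin = -1e30, tmax = 1e30;
      for (int i = 0; i < n; ++i) {
        if (std::fabs(d[i]) < 1e-12) continue;
        double lo = (lb[i] - x[i]) / d[i];
        double hi = (ub[i] - x[i]) / d[i];
        if (d[i] > 0) {
          if (lo > tmin) tmin = lo;
          if (hi < tmax) tmax = hi;
        } else {
          if (hi > tmin) tmin = hi;
          if (lo < tmax) tmax = lo;
        }
      }
      if (tmax - tmin > 1e-12) {
        double t = tmin + unif_rand() * (tmax - tmin);
        for (int i = 0; i < n; ++i) {
          x[i] += t * d[i];
          if (x[i] < lb[i]) x[i] = lb[i];
          if (x[i] > ub[i]) x[i] = ub[i];
        }
        moved = true;
      }
    }
    if (moved) {
      cnt += 1.0;
      for (int i = 0; i < n; ++i)
        center[i] += (x[i] - center[i]) / cnt;
    }
    if (step >= burn) {
      if (++since == thinning) {
        for (int i = 0; i < n; ++i) out(recorded, i) = x[i];
        ++recorded;
        since = 0;
      }
    }
  }
  return out;
}
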