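#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized squared-hinge linear SVC
// (Hsieh et al. 2008; the algorithm behind liblinear's L2R_L2LOSS_SVC_DUAL),
// with the usual shrinking heuristic on the active set:
//
//   min_w  0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w.x_i)^2
//
// y in {-1,+1}; the per-sample cost C_i carries class weights. The intercept
// is an augmented constant row appended by the R wrapper, so Xt already
// includes it. Xt is features x samples so each sample is a contiguous
// column. `skip` (0-based, -1 = none) excludes one feature row without
// copying the matrix: with that row masked, w[skip] stays 0, which is
// exactly the model fit without the feature. `alpha0` warm-starts the dual
// variables (used by drop-one feature selection, where consecutive fits
// differ by one feature).
//
// Determinism: the coordinate sweep order comes from a private LCG seeded by
// `perm_seed`, so fits neither consume nor disturb R's RNG stream.

static inline double lcg_next(uint64_t &state) {
  state = state * 6364136223846793005ULL + 1442695040888963407ULL;
  return (double)(state >> 11) / 9007199254740992.0; // [0,1)
}

// [[Rcpp::export(name = ".dcd_svc")]]
List dcd_svc(NumericMatrix Xt, NumericVector y, NumericVector Ci,
             int max_iter, double tol, int perm_seed,
             int skip, Nullable<NumericVector> alpha0) {
  const int p = Xt.nrow(), n = Xt.ncol();
  const double *X = REAL(Xt);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> w(p, 0.0), alpha(n, 0.0), qii(n);

  if (alpha0.isNotNull()) {
    NumericVector a0(alpha0.get());
    for (int i = 0; i < n; ++i) alpha[i] = a0[i];
  }
  for (int i = 0; i < n; ++i) {
    const double *xi = X + (size_t)i * p;
    double s = 0.0;
    for (int j = 0; j < p; ++j) if (j != skip) s += xi[j] * xi[j];
    qii[i] = s + 1.0 / (2.0 * Ci[i]); // D_ii term for the squared hinge
    if (alpha[i] != 0.0) {
      const double ay = alpha[i] * y[i];
      for (int j = 0; j < p; ++j) if (j != skip) w[j] += ay * xi[j];
    }
  }

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  int active = n;
  double pgmax_old = INF;
  uint64_t rng = (uint64_t)perm_seed * 2654435761ULL + 1ULL;

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    for (int i = active - 1; i > 0; --i) { // Fisher-Yates on the active set
      int j = (int)(lcg_next(rng) * (i + 1));
      std::swap(idx[i], idx[j]);
    }
    double pgmax_new = -INF, pgmin_new = INF;
    for (int k = 0; k < active; ++k) {
      const int i = idx[k];
      const double *xi = X + (size_t)i * p;
      double wx = 0.0;
      for (int j = 0; j < p; ++j) if (j != skip) wx += w[j] * xi[j];
      const double G = y[i] * wx - 1.0 + alpha[i] / (2.0 * Ci[i]);
      double pg = G;
      if (alpha[i] == 0.0) {
        if (G > pgmax_old) { // persistently inactive: shrink it away
          --active;
          std::swap(idx[k], idx[active]);
          --k;
          continue;
        }
        if (G > 0.0) pg = 0.0;
      }
      if (pg > pgmax_new) pgmax_new = pg;
      if (pg < pgmin_new) pgmin_new = pg;
      if (pg != 0.0) {
        const double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        alpha[i] = a_new;
        const double d = (a_new - a_old) * y[i];
        if (d != 0.0)
          for (int j = 0; j < p; ++j) if (j != skip) w[j] += d * xi[j];
      }
    }
    if (pgmax_new - pgmin_new <= tol) {
      if (active == n) { ++iter; break; }
      active = n; // re-examine shrunk variables before declaring victory
      pgmax_old = INF;
      continue;
    }
    pgmax_old = (pgmax_new <= 0.0) ? INF : pgmax_new;
  }
  if (skip >= 0) w[skip] = 0.0;
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iter"] = iter);
}
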