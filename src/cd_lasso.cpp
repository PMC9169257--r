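#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Coordinate descent for
//   min_g 0.5 g'Gg - c'g + lambda * sum_j w_j |g_j|   (+ s'g = 0 if constrained)
// where G = M'M/n and c = M'y/n for a centered design M.  The linear
// constraint (the log-contrast zero-sum) is handled by an augmented
// Lagrangian outer loop: mu tracks the multiplier, rho is escalated when
// the violation stalls.  Collinear columns of M (nested tree nodes) make
// G singular; coordinate descent still converges to a minimizer.
// [[Rcpp::export]]
NumericVector cd_lasso_al(NumericMatrix G, NumericVector c, NumericVector s,
                          double lambda, NumericVector w, NumericVector gamma0,
                          bool constrained, double tol = 1e-7,
                          int max_sweeps = 2000, double rho0 = 1.0) {
  const int q = c.size();
  NumericVector g = clone(gamma0);
  double mu = 0.0, rho = constrained ? rho0 : 0.0;

  std::vector<double> Gg(q, 0.0);
  for (int j = 0; j < q; ++j)
    if (g[j] != 0.0)
      for (int i = 0; i < q; ++i) Gg[i] += G(i, j) * g[j];
  double sg = 0.0;
  for (int j = 0; j < q; ++j) sg += s[j] * g[j];

  const int outer_max = constrained ? 200 : 1;
  double prev_viol = R_PosInf;
  bool inner_ok = false;
  for (int outer = 0; outer < outer_max; ++outer) {
    inner_ok = false;
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      double maxdiff = 0.0;
      for (int j = 0; j < q; ++j) {
        const double gj = g[j];
        const double qj = G(j, j) + rho * s[j] * s[j];
        if (qj <= 0.0) continue;  // empty predictor column
        const double r = c[j] - (Gg[j] - G(j, j) * gj) - mu * s[j]
                         - rho * s[j] * (sg - s[j] * gj);
        const double thr = lambda * w[j];
        double newg;
        if (r > thr)       newg = (r - thr) / qj;
        else if (r < -thr) newg = (r + thr) / qj;
        else               newg = 0.0;
        const double d = newg - gj;
        if (d != 0.0) {
          for (int i = 0; i < q; ++i) Gg[i] += G(i, j) * d;
          sg += s[j] * d;
          g[j] = newg;
          const double ad = std::fabs(d);
          if (ad > maxdiff) maxdiff = ad;
        }
      }
      if (maxdiff < tol) { inner_ok = true; break; }
    }
    if (!constrained) break;
    const double viol = std::fabs(sg);
    if (viol < 1e-10) break;
    mu += rho * sg;
    if (viol > 0.25 * prev_viol && rho < 1e8) rho *= 10.0;
    prev_viol = viol;
  }

  g.attr("constraint_violation") = sg;
  g.attr("converged") = inner_ok;
  return g;
}
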