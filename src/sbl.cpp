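#include <Rcpp.h>
using namespace Rcpp;

// Sparse Bayesian learning over the step basis (GADA stage 1).
//
// Model: y_i = beta0 + (F w)_i + e_i, e ~ N(0, sigma2 I), where column j of
// F is the unit step starting at position j+1 (j = 1..n-1). Priors
// w_j | alpha_j ~ N(0, 1/alpha_j), alpha_j ~ Gamma(a, b -> 0). EM on the
// alpha hyperparameters with exact posterior moments of w.
//
// Per-iteration cost is O(n): the Gram matrix G = F'F has entries
// n - max(j,k), whose inverse T is tridiagonal (for an active subset
// j_1 < ... < j_q, with g_a = j_{a+1} - j_a and g_q = n - j_q:
// T_aa = 1/g_a + 1/g_{a-1} [no left term for a = 1], T_{a,a+1} = -1/g_a).
// By Woodbury, with A = diag(alpha) and K = A^{-1} + sigma2 * T (SPD
// tridiagonal),
//   Sigma = (G/sigma2 + A)^{-1} = A^{-1} - A^{-1} K^{-1} A^{-1}
//   mu_a  = (z_a - v_a) / (sigma2 * alpha_a),  v = K^{-1} (z / alpha)
// where z = F'(y - beta0). diag(K^{-1}) comes from the standard two-sided
// elimination recurrences. Components whose alpha exceeds alphaMax are
// pruned from the active set (their weight is exactly zero thereafter).

// [[Rcpp::export(name = ".sblCore")]]
List sblCore(NumericVector y, double aPrior, double sigma2, double tol,
             int maxIter, double alphaMax) {
  const int n = y.size();
  const int m = n - 1;
  if (n < 2) stop("signal must have length >= 2");
  for (int i = 0; i < n; ++i)
    if (!R_finite(y[i])) stop("non-finite values in signal");
  if (sigma2 <= 0) stop("sigma2 must be positive");

  std::vector<int> act(m);            // active breakpoint positions (1-based)
  for (int j = 0; j < m; ++j) act[j] = j + 1;
  std::vector<double> alpha(m, 1.0);
  NumericVector wFull(m, 0.0), wPrev(m, 0.0), alphaFull(m, 1.0);
  double beta0 = mean(y);
  bool converged = false;
  int iter = 0;

  // tail sums of y, so that z_j = Sy[j] - (n - j) * beta0 in O(1)
  std::vector<double> Sy(n);
  Sy[n - 1] = y[n - 1];
  for (int i = n - 2; i >= 0; --i) Sy[i] = Sy[i + 1] + y[i];
  const double ySum = Sy[0];

  std::vector<double> g, Td, z, u, Kd, Ko, dfw, ebw, v, mu, Sdiag;
  while (iter < maxIter) {
    ++iter;
    int q = act.size();
    // intercept given current weights: beta0 = mean(y - F w), where
    // sum(F w) = sum_j w_j * (n - j)
    {
      double sFw = 0.0;
      for (int a2 = 0; a2 < q; ++a2)
        sFw += wFull[act[a2] - 1] * (n - act[a2]);
      beta0 = (ySum - sFw) / n;
    }
    if (q == 0) { converged = true; break; }

    g.assign(q, 0.0); Td.assign(q, 0.0); z.assign(q, 0.0); u.assign(q, 0.0);
    for (int a2 = 0; a2 < q; ++a2) {
      g[a2] = (a2 < q - 1 ? act[a2 + 1] : n) - act[a2];
      Td[a2] = 1.0 / g[a2] + (a2 > 0 ? 1.0 / g[a2 - 1] : 0.0);
      z[a2] = Sy[act[a2]] - (n - act[a2]) * beta0;
      u[a2] = z[a2] / alpha[a2];
    }
    Kd.assign(q, 0.0); Ko.assign(q, 0.0);
    for (int a2 = 0; a2 < q; ++a2) {
      Kd[a2] = 1.0 / alpha[a2] + sigma2 * Td[a2];
      if (a2 < q - 1) Ko[a2] = -sigma2 / g[a2];
    }
    // Thomas solve K v = u and two-sided elimination for diag(K^{-1})
    dfw.assign(q, 0.0); ebw.assign(q, 0.0); v.assign(q, 0.0);
    std::vector<double> rhs(u);
    dfw[0] = Kd[0];
    for (int a2 = 1; a2 < q; ++a2) {
      double l = Ko[a2 - 1] / dfw[a2 - 1];
      dfw[a2] = Kd[a2] - l * Ko[a2 - 1];
      rhs[a2] -= l * rhs[a2 - 1];
    }
    v[q - 1] = rhs[q - 1] / dfw[q - 1];
    for (int a2 = q - 2; a2 >= 0; --a2)
      v[a2] = (rhs[a2] - Ko[a2] * v[a2 + 1]) / dfw[a2];
    ebw[q - 1] = Kd[q - 1];
    for (int a2 = q - 2; a2 >= 0; --a2)
      ebw[a2] = Kd[a2] - Ko[a2] * Ko[a2] / ebw[a2 + 1];

    mu.assign(q, 0.0); Sdiag.assign(q, 0.0);
    for (int a2 = 0; a2 < q; ++a2) {
      mu[a2] = (z[a2] - v[a2]) / (sigma2 * alpha[a2]);
      double kinv = 1.0 / (dfw[a2] + ebw[a2] - Kd[a2]);
      double s = 1.0 / alpha[a2] - kinv / (alpha[a2] * alpha[a2]);
      Sdiag[a2] = s > 0 ? s : 0.0;
    }
    // alpha update and pruning
    std::vector<int> act0(act.begin(), act.begin() + q);
    std::vector<int> keep;
    keep.reserve(q);
    for (int a2 = 0; a2 < q; ++a2) wFull[act0[a2] - 1] = 0.0;
    for (int a2 = 0; a2 < q; ++a2) {
      double denom = mu[a2] * mu[a2] + Sdiag[a2];
      double anew = denom > 0 ? (1.0 + 2.0 * aPrior) / denom : alphaMax;
      if (anew < alphaMax) {
        alpha[keep.size()] = anew;
        act[keep.size()] = act[a2];
        keep.push_back(a2);
        wFull[act[keep.size() - 1] - 1] = mu[a2];
      }
      alphaFull[act[a2] - 1] = anew > alphaMax ? alphaMax : anew;
    }
    act.resize(keep.size());
    alpha.resize(keep.size());
    // note act/alpha were compacted in place above
    double dmax = 0.0;
    for (int a2 = 0; a2 < q; ++a2) {
      int j = act0[a2] - 1;
      double d = std::fabs(wFull[j] - wPrev[j]);
      if (d > dmax) dmax = d;
      wPrev[j] = wFull[j];
    }
    if (dmax < tol) { converged = true; break; }
  }
  IntegerVector active(act.size());
  for (size_t a2 = 0; a2 < act.size(); ++a2) active[a2] = act[a2];
  return List::create(_["w"] = wFull, _["alpha"] = alphaFull,
                      _["active"] = active, _["beta0"] = beta0,
                      _["iterations"] = iter, _["converged"] = converged);
}
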