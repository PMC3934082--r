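#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Coordinate descent for min ||Ac - y||_2^2 + lambda ||c||_1, parameterised by
// the Gram matrix G = A'A, the correlation vector Aty = A'y and yty = ||y||^2
// (covariance updates: the design matrix itself is never touched here).
// The duality gap uses the scaled dual feasible point nu = 2 s (Ac - y),
// s = min(1, lambda / ||2 A'(Ac - y)||_inf), with dual objective
// g(nu) = -nu'nu/4 - nu'y; all terms are Gram-expressible.
// [[Rcpp::export(name = ".cd_lasso_gram")]]
List cd_lasso_gram(NumericMatrix G, NumericVector Aty, double yty,
                   double lambda, double gapTol, int maxIter) {
  const int n = G.ncol();
  NumericVector c(n);       // coefficients, start at zero
  NumericVector q(n);       // q = G c
  double gap = R_PosInf, obj = R_PosInf;
  bool converged = false;
  int sweep = 0;
  const double thr = lambda / 2.0;

  for (sweep = 1; sweep <= maxIter; ++sweep) {
    double maxDelta = 0.0;
    for (int j = 0; j < n; ++j) {
      const double gjj = G(j, j);
      const double cold = c[j];
      double cnew;
      if (gjj <= 0.0) {
        cnew = 0.0;
      } else {
        const double rho = Aty[j] - q[j] + gjj * cold; // partial correlation
        cnew = soft(rho, thr) / gjj;
      }
      const double d = cnew - cold;
      if (d != 0.0) {
        c[j] = cnew;
        for (int k = 0; k < n; ++k) q[k] += d * G(k, j);
        double ad = std::fabs(d);
        if (ad > maxDelta) maxDelta = ad;
      }
    }
    // duality gap check (cheap relative to the sweep: all O(n) dot products)
    double cq = 0.0, cAty = 0.0, l1 = 0.0, maxAtr = 0.0;
    for (int j = 0; j < n; ++j) {
      cq += c[j] * q[j];
      cAty += c[j] * Aty[j];
      l1 += std::fabs(c[j]);
      double atr = std::fabs(q[j] - Aty[j]); // |A'(Ac - y)|_j
      if (atr > maxAtr) maxAtr = atr;
    }
    double rsq = cq - 2.0 * cAty + yty;      // ||Ac - y||^2
    if (rsq < 0.0) rsq = 0.0;
    obj = rsq + lambda * l1;
    double s = 1.0;
    if (2.0 * maxAtr > lambda && maxAtr > 0.0) s = lambda / (2.0 * maxAtr);
    const double rty = cAty - yty;           // (Ac - y)'y
    const double dualObj = -(s * s) * rsq - 2.0 * s * rty;
    gap = obj - dualObj;
    if (gap < 0.0) gap = 0.0;                // round-off guard
    if (gap <= gapTol * (1.0 + std::fabs(obj))) {
      converged = true;
      break;
    }
    if (maxDelta == 0.0) break;              // fixed point; gap is what it is
  }
  if (sweep > maxIter) sweep = maxIter;

  return List::create(_["coefficients"] = c,
                      _["objective"] = obj,
                      _["gap"] = gap,
                      _["iterations"] = sweep,
                      _["converged"] = converged);
}

// Cyclic coordinate ascent for  max  lin'a - a'Qa/2  s.t.  0 <= a <= upper.
// Q symmetric positive semidefinite. A zero diagonal entry implies (psd) a
// zero row, so the objective is linear in that coordinate: it goes to the
// bound selected by the sign of the linear term. Stationarity is certified by
// the projected-gradient residual ||a - clip(a + g, 0, upper)||_inf.
// [[Rcpp::export(name = ".boxqp_ca")]]
List boxqp_ca(NumericMatrix Q, NumericVector lin, double upper,
              double tol, int maxIter) {
  const int n = Q.ncol();
  NumericVector a(n), g(n);
  for (int j = 0; j < n; ++j) g[j] = lin[j]; // g = lin - Q a, a = 0
  double res = R_PosInf;
  bool converged = false;
  int sweep = 0;

  for (sweep = 1; sweep <= maxIter; ++sweep) {
    for (int j = 0; j < n; ++j) {
      const double qjj = Q(j, j);
      const double aold = a[j];
      double anew;
      if (qjj <= 0.0) {
        anew = (g[j] > 0.0) ? upper : (g[j] < 0.0 ? 0.0 : aold);
      } else {
        anew = aold + g[j] / qjj;
        if (anew < 0.0) anew = 0.0;
        else if (anew > upper) anew = upper;
      }
      const double d = anew - aold;
      if (d != 0.0) {
        a[j] = anew;
        for (int k = 0; k < n; ++k) g[k] -= d * Q(k, j);
      }
    }
    res = 0.0;
    for (int j = 0; j < n; ++j) {
      double p = a[j] + g[j];
      if (p < 0.0) p = 0.0;
      else if (p > upper) p = upper;
      const double v = std::fabs(a[j] - p);
      if (v > res) res = v;
    }
    if (res <= tol) {
      converged = true;
      break;
    }
  }
  if (sweep > maxIter) sweep = maxIter;

  double objective = 0.0;
  for (int j = 0; j < n; ++j) objective += a[j] * (lin[j] + g[j]);
  // lin + g = 2 lin - Q a, so a'(lin + g) = 2 (lin'a - a'Qa/2)
  objective /= 2.0;

  return List::create(_["alpha"] = a,
                      _["objective"] = objective,
                      _["residual"] = res,
                      _["iterations"] = sweep,
                      _["converged"] = converged);
}
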