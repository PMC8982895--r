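#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the weighted Lasso
//   min_lambda (1/n) ||u - F lambda||^2 + 2 * sum_k thr_k |lambda_k|
// thr_k is the full per-coordinate threshold (sigma^2 * r_{n,k}).
// Soft-thresholding update per coordinate; residual maintained in place.
// Converges when the largest coefficient change in a sweep <= tol.

inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export]]
List cd_lasso(const NumericMatrix& F, const NumericVector& u,
              const NumericVector& thr, NumericVector lambda0,
              double tol, int max_sweeps) {
  const int n = F.nrow(), p = F.ncol();
  NumericVector lambda = clone(lambda0);
  std::vector<double> res(n);
  std::vector<double> colnorm(p); // ||F_k||^2 / n

  for (int i = 0; i < n; ++i) res[i] = u[i];
  for (int k = 0; k < p; ++k) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      s += F(i, k) * F(i, k);
      res[i] -= F(i, k) * lambda[k];
    }
    colnorm[k] = s / n;
  }

  bool converged = false;
  int sweep = 0;
  for (sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxdelta = 0.0;
    for (int k = 0; k < p; ++k) {
      if (colnorm[k] == 0.0) { // empty column: only the penalty remains
        if (lambda[k] != 0.0) { maxdelta = R_PosInf; lambda[k] = 0.0; }
        continue;
      }
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += F(i, k) * res[i];
      rho = rho / n + colnorm[k] * lambda[k];
      double lk = soft(rho, thr[k]) / colnorm[k];
      double d = lk - lambda[k];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) res[i] -= F(i, k) * d;
        lambda[k] = lk;
        double ad = std::abs(d);
        if (ad > maxdelta) maxdelta = ad;
      }
    }
    if (maxdelta <= tol) { converged = true; ++sweep; break; }
  }

  return List::create(_["lambda"] = lambda, _["converged"] = converged,
                      _["sweeps"] = sweep);
}
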