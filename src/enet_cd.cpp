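// Cyclic coordinate-descent kernel for the elastic net (covariance-update
// form). Mirrors the reference R implementation in R/enet.R exactly:
// converged when the largest coefficient update in a sweep is < tol.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List enet_cd_cpp(NumericMatrix XtX, NumericVector Xty, double alpha,
                 double lambda, NumericVector beta0, double tol,
                 int max_sweeps) {
  const int p = Xty.size();
  NumericVector beta = clone(beta0);
  NumericVector dg(p), denom(p);
  for (int j = 0; j < p; ++j) {
    dg[j] = XtX(j, j);
    denom[j] = dg[j] + lambda * (1.0 - alpha);
  }
  const double thr = lambda * alpha;
  int sweeps = 0;
  bool converged = false;
  while (sweeps < max_sweeps) {
    ++sweeps;
    double maxdel = 0.0;
    for (int j = 0; j < p; ++j) {
      const double bj = beta[j];
      double dot = 0.0;
      for (int k = 0; k < p; ++k) dot += XtX(j, k) * beta[k];
      const double rho = Xty[j] - dot + dg[j] * bj;
      double bnew = 0.0;
      if (denom[j] > 0.0) {
        const double z = std::fabs(rho) - thr;
        if (z > 0.0) bnew = (rho > 0.0 ? z : -z) / denom[j];
      }
      if (bnew != bj) {
        beta[j] = bnew;
        const double d = std::fabs(bnew - bj);
        if (d > maxdel) maxdel = d;
      }
    }
    if (maxdel < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = beta, _["sweeps"] = sweeps,
                      _["converged"] = converged);
}
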