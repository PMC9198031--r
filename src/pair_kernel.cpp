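#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Stable log(1 + exp(x)); finite for |x| up to well beyond 700.
static inline double log1pexp_c(double x) {
  if (x <= -37.0) return std::exp(x);
  if (x <= 18.0)  return std::log1p(std::exp(x));
  if (x <= 33.3)  return x + std::exp(-x);
  return x;
}

// Stable logistic sigma(x) = 1 / (1 + exp(-x)).
static inline double sigmoid_c(double x) {
  if (x >= 0.0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Pairwise conditional logistic quantities for one site, streaming over all
// (case, control) pairs without materializing the difference matrix.
//
// For each pair the linear predictor is computed as beta . (x_case - x_ctrl),
// accumulated coordinate-by-coordinate so that a column with identical case
// and control values (e.g. a synthetic intercept) contributes an exact 0.0
// and the result is bit-identical under intercept shifts.
//
// order: 0 = log-likelihood only, 1 = + score, 2 = + Hessian.
// [[Rcpp::export]]
List pair_eval_cpp(NumericMatrix Xcase, NumericMatrix Xctrl,
                   NumericVector beta, int order) {
  const int n1 = Xcase.nrow(), n0 = Xctrl.nrow(), p = beta.size();
  double ll = 0.0;
  NumericVector grad(p);
  NumericMatrix hess(p, p);
  if (n1 == 0 || n0 == 0) {
    return List::create(_["ll"] = ll, _["grad"] = grad, _["hess"] = hess,
                        _["d_k"] = 0.0);
  }
  std::vector<double> d(p);
  const double *xc = REAL(Xcase), *xl = REAL(Xctrl), *b = REAL(beta);
  double *g = REAL(grad), *h = REAL(hess);
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n0; ++j) {
      double z = 0.0;
      for (int l = 0; l < p; ++l) {
        double dl = xc[i + (R_xlen_t)l * n1] - xl[j + (R_xlen_t)l * n0];
        d[l] = dl;
        z += b[l] * dl;
      }
      // share e = exp(-|z|) between -log(1+exp(-z)) and sigma(-z):
      //   z >= 0: ll pair term = -log1p(e),      sigma(-z) = e / (1 + e)
      //   z <  0: ll pair term = z - log1p(e),   sigma(-z) = 1 / (1 + e)
      double az = std::fabs(z);
      double e = (az > 745.0) ? 0.0 : std::exp(-az);
      double l1p = std::log1p(e);
      ll -= (z >= 0.0) ? l1p : (l1p - z);
      if (order >= 1) {
        double w = (z >= 0.0) ? e / (1.0 + e) : 1.0 / (1.0 + e);
        for (int l = 0; l < p; ++l) g[l] += w * d[l];
        if (order >= 2) {
          double c = w * (1.0 - w);
          for (int l = 0; l < p; ++l) {
            double cdl = c * d[l];
            for (int m = l; m < p; ++m) h[l + (R_xlen_t)m * p] -= cdl * d[m];
          }
        }
      }
    }
  }
  if (order >= 2) {
    for (int l = 0; l < p; ++l)
      for (int m = l + 1; m < p; ++m)
        h[m + (R_xlen_t)l * p] = h[l + (R_xlen_t)m * p];
  }
  return List::create(_["ll"] = ll, _["grad"] = grad, _["hess"] = hess,
                      _["d_k"] = (double)n1 * (double)n0);
}

// Building blocks of the Hajek-projection sandwich for one site at beta:
//  - Ucase / Uctrl: per-subject aggregated pair scores (sum of s_ij over the
//    pairs containing the subject), s_ij = (x_i - x_j) * sigma(-beta.(x_i-x_j))
//  - pair_outer: sum over pairs of s_ij s_ij^T (removes the double-counted
//    per-pair variance term in B = sum U U^T over cases and controls).
// [[Rcpp::export]]
List pair_sandwich_cpp(NumericMatrix Xcase, NumericMatrix Xctrl,
                       NumericVector beta) {
  const int n1 = Xcase.nrow(), n0 = Xctrl.nrow(), p = beta.size();
  NumericMatrix Ucase(n1, p), Uctrl(n0, p), pair_outer(p, p);
  if (n1 == 0 || n0 == 0)
    return List::create(_["Ucase"] = Ucase, _["Uctrl"] = Uctrl,
                        _["pair_outer"] = pair_outer);
  std::vector<double> d(p), s(p);
  const double *xc = REAL(Xcase), *xl = REAL(Xctrl), *b = REAL(beta);
  double *uc = REAL(Ucase), *ul = REAL(Uctrl), *po = REAL(pair_outer);
  for (int i = 0; i < n1; ++i) {
    for (int j = 0; j < n0; ++j) {
      double z = 0.0;
      for (int l = 0; l < p; ++l) {
        double dl = xc[i + (R_xlen_t)l * n1] - xl[j + (R_xlen_t)l * n0];
        d[l] = dl;
        z += b[l] * dl;
      }
      double w = sigmoid_c(-z);
      for (int l = 0; l < p; ++l) {
        double sl = w * d[l];
        s[l] = sl;
        uc[i + (R_xlen_t)l * n1] += sl;
        ul[j + (R_xlen_t)l * n0] += sl;
      }
      for (int l = 0; l < p; ++l)
        for (int m = l; m < p; ++m)
          po[l + (R_xlen_t)m * p] += s[l] * s[m];
    }
  }
  for (int l = 0; l < p; ++l)
    for (int m = l + 1; m < p; ++m)
      po[m + (R_xlen_t)l * p] = po[l + (R_xlen_t)m * p];
  return List::create(_["Ucase"] = Ucase, _["Uctrl"] = Uctrl,
                      _["pair_outer"] = pair_outer);
}
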