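#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-loss (hinge) linear SVM:
//   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
// with the bias folded in as a constant augmented feature. Deterministic
// cyclic sweeps (no permutation) so a fit is a pure function of its inputs.
// X: n x d, y in {-1, +1}. Returns the (d+1)-vector (w, b).
// [[Rcpp::export(name = ".svm_dcd_fit")]]
NumericVector svm_dcd_fit(NumericMatrix X, NumericVector y, double C,
                          int max_iter = 1000, double tol = 1e-6) {
  const int n = X.nrow();
  const int d = X.ncol();
  std::vector<double> w(d + 1, 0.0);   // last entry is the bias weight
  std::vector<double> alpha(n, 0.0);
  std::vector<double> Qii(n);
  for (int i = 0; i < n; ++i) {
    double s = 1.0;                    // augmented constant feature
    for (int j = 0; j < d; ++j) s += X(i, j) * X(i, j);
    Qii[i] = s;
  }
  for (int iter = 0; iter < max_iter; ++iter) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      double wx = w[d];
      for (int j = 0; j < d; ++j) wx += w[j] * X(i, j);
      double G = y[i] * wx - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      if (std::fabs(PG) > max_pg) max_pg = std::fabs(PG);
      if (PG != 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - G / Qii[i], 0.0), C);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        for (int j = 0; j < d; ++j) w[j] += delta * X(i, j);
        w[d] += delta;
      }
    }
    if (max_pg < tol) break;
  }
  return NumericVector(w.begin(), w.end());
}

// Decision values w.x + b for rows of X given the (d+1) coefficient vector.
// [[Rcpp::export(name = ".svm_decision")]]
NumericVector svm_decision(NumericMatrix X, NumericVector coef) {
  const int n = X.nrow();
  const int d = X.ncol();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = coef[d];
    for (int j = 0; j < d; ++j) s += coef[j] * X(i, j);
    out[i] = s;
  }
  return out;
}
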