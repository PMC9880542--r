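// Epsilon-insensitive support vector regression with an RBF kernel, solved
// by cyclic coordinate descent on the bias-free dual (a constant 1 added to
// the kernel absorbs the intercept, removing the equality constraint):
//   min_beta 1/2 beta' K beta - beta' y + eps * ||beta||_1,  |beta_i| <= C.
// Each coordinate has the closed-form soft-threshold/clip update, so the
// sweep converges monotonically. n is a few hundred here; the dense kernel
// matrix is cheap.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double rbf(const NumericMatrix& A, int i,
                         const NumericMatrix& B, int j, double gamma) {
  double s = 0.0;
  for (int k = 0; k < A.ncol(); ++k) {
    double d = A(i, k) - B(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s) + 1.0; // +1 = implicit regularised bias
}

// [[Rcpp::export(name = ".svr_fit")]]
NumericVector svr_fit(NumericMatrix X, NumericVector y, double gamma,
                      double C, double eps, double tol, int max_sweeps) {
  const int n = X.nrow();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      K(i, j) = K(j, i) = rbf(X, i, X, j, gamma);
    }
  }
  NumericVector beta(n, 0.0), f(n, 0.0); // f = K beta
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double max_delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - (f[i] - K(i, i) * beta[i]);
      double b;
      if (r > eps) b = (r - eps) / K(i, i);
      else if (r < -eps) b = (r + eps) / K(i, i);
      else b = 0.0;
      if (b > C) b = C;
      if (b < -C) b = -C;
      double d = b - beta[i];
      if (d != 0.0) {
        beta[i] = b;
        for (int j = 0; j < n; ++j) f[j] += K(i, j) * d;
        double ad = std::fabs(d);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) break;
  }
  return beta;
}

// [[Rcpp::export(name = ".svr_predict")]]
NumericVector svr_predict(NumericMatrix Xnew, NumericMatrix Xtrain,
                          NumericVector beta, double gamma) {
  const int m = Xnew.nrow(), n = Xtrain.nrow();
  NumericVector out(m, 0.0);
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      if (beta[j] != 0.0) s += beta[j] * rbf(Xnew, i, Xtrain, j, gamma);
    }
    out[i] = s;
  }
  return out;
}
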