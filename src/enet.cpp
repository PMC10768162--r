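#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the penalised least-squares objective
//
//   sum_i (y_i - b0 - x_i' beta)^2 + lambda * sum_j ( alpha*|beta_j|
//                                                   + 0.5*(1-alpha)*beta_j^2 )
//
// The intercept is unpenalised: X and y are centred internally, so b0 is
// recovered as ybar - xbar' beta.  Note the residual term carries no 1/(2n)
// factor, so lambda here is 2n times glmnet's lambda.
//
// Subgradient stationarity for coordinate j (partial residual r):
//   beta_j = S(x_j'r + x_j'x_j * beta_j, lambda*alpha/2) /
//            (x_j'x_j + lambda*(1-alpha)/2)

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// one solve at a given lambda, warm-started from beta / r (both modified)
static bool cd_solve(const std::vector<double>& Xc, int n, int p,
                     const std::vector<double>& xx, double lambda,
                     double alpha, int max_iter, double tol,
                     std::vector<double>& beta, std::vector<double>& r,
                     int& iters, double& last_delta) {
  const double l1 = lambda * alpha / 2.0;
  const double l2 = lambda * (1.0 - alpha) / 2.0;
  double delta = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    delta = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0.0) { beta[j] = 0.0; continue; }
      const double* xj = &Xc[(size_t)j * n];
      double xr = 0.0;
      for (int i = 0; i < n; ++i) xr += xj[i] * r[i];
      double z = xr + xx[j] * beta[j];
      double bj = soft(z, l1) / (xx[j] + l2);
      double d = bj - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
        double ad = std::fabs(d);
        if (ad > delta) delta = ad;
        beta[j] = bj;
      }
    }
    if (delta < tol) { ++it; break; }
  }
  iters = it;
  last_delta = delta;
  return delta < tol;
}

static void centre(NumericMatrix X, NumericVector y, int n, int p,
                   std::vector<double>& Xc, std::vector<double>& xm,
                   std::vector<double>& xx, std::vector<double>& yc,
                   double& ym) {
  ym = 0.0;
  for (int i = 0; i < n; ++i) ym += y[i];
  ym /= n;
  yc.resize(n);
  for (int i = 0; i < n; ++i) yc[i] = y[i] - ym;
  Xc.resize((size_t)n * p);
  xm.resize(p);
  xx.resize(p);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += X(i, j);
    m /= n;
    xm[j] = m;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j) - m;
      Xc[(size_t)j * n + i] = v;
      ss += v * v;
    }
    xx[j] = ss;
  }
}

// [[Rcpp::export(name = ".enet_cd")]]
List enet_cd(NumericMatrix X, NumericVector y, double lambda, double alpha,
             int max_iter, double tol) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> Xc, xm, xx, r;
  double ym;
  centre(X, y, n, p, Xc, xm, xx, r, ym);
  std::vector<double> beta(p, 0.0);
  int iters = 0;
  double last_delta = 0.0;
  bool conv = cd_solve(Xc, n, p, xx, lambda, alpha, max_iter, tol,
                       beta, r, iters, last_delta);
  double b0 = ym;
  for (int j = 0; j < p; ++j) b0 -= beta[j] * xm[j];
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = b0,
                      _["iter"] = iters,
                      _["converged"] = conv,
                      _["last_delta"] = last_delta);
}

// Warm-started solution path over a decreasing lambda sequence.
// Returns a p x nlambda coefficient matrix plus intercepts.
// [[Rcpp::export(name = ".enet_cd_path")]]
List enet_cd_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                  double alpha, int max_iter, double tol) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  std::vector<double> Xc, xm, xx, r;
  double ym;
  centre(X, y, n, p, Xc, xm, xx, r, ym);
  std::vector<double> beta(p, 0.0);
  NumericMatrix B(p, nl);
  NumericVector b0(nl);
  LogicalVector conv(nl);
  for (int l = 0; l < nl; ++l) {
    int iters = 0;
    double last_delta = 0.0;
    conv[l] = cd_solve(Xc, n, p, xx, lambdas[l], alpha, max_iter, tol,
                       beta, r, iters, last_delta);
    double ic = ym;
    for (int j = 0; j < p; ++j) {
      B(j, l) = beta[j];
      ic -= beta[j] * xm[j];
    }
    b0[l] = ic;
  }
  return List::create(_["beta"] = B, _["intercept"] = b0,
                      _["converged"] = conv);
}
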