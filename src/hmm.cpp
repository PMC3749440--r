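#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dnorm_c(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// Scaled forward-backward E-step for a 2-state Gaussian-emission HMM.
// Returns the log-likelihood and the sufficient statistics needed by the
// M-step: occupancies, first and second emission moments per state,
// expected transition counts, and the initial-state posteriors.
// [[Rcpp::export]]
List hmm_estep_cpp(NumericVector x, NumericVector mu, NumericVector sigma,
                   NumericMatrix A, NumericVector pi0) {
  int T = x.size();
  NumericMatrix alpha(T, 2), beta(T, 2), B(T, 2);
  NumericVector cvec(T);
  for (int t = 0; t < T; ++t) {
    B(t, 0) = dnorm_c(x[t], mu[0], sigma[0]) + 1e-300;
    B(t, 1) = dnorm_c(x[t], mu[1], sigma[1]) + 1e-300;
  }
  // forward with scaling
  alpha(0, 0) = pi0[0] * B(0, 0);
  alpha(0, 1) = pi0[1] * B(0, 1);
  double c = alpha(0, 0) + alpha(0, 1);
  cvec[0] = c;
  alpha(0, 0) /= c; alpha(0, 1) /= c;
  for (int t = 1; t < T; ++t) {
    double a0 = (alpha(t - 1, 0) * A(0, 0) + alpha(t - 1, 1) * A(1, 0)) * B(t, 0);
    double a1 = (alpha(t - 1, 0) * A(0, 1) + alpha(t - 1, 1) * A(1, 1)) * B(t, 1);
    c = a0 + a1;
    cvec[t] = c;
    alpha(t, 0) = a0 / c; alpha(t, 1) = a1 / c;
  }
  // backward, same scaling
  beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double b0 = A(0, 0) * B(t + 1, 0) * beta(t + 1, 0) +
                A(0, 1) * B(t + 1, 1) * beta(t + 1, 1);
    double b1 = A(1, 0) * B(t + 1, 0) * beta(t + 1, 0) +
                A(1, 1) * B(t + 1, 1) * beta(t + 1, 1);
    beta(t, 0) = b0 / cvec[t + 1];
    beta(t, 1) = b1 / cvec[t + 1];
  }
  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(cvec[t]);

  double N0 = 0, N1 = 0, sx0 = 0, sx1 = 0, sxx0 = 0, sxx1 = 0;
  NumericMatrix xi(2, 2);
  NumericVector g1(2);
  for (int t = 0; t < T; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double gg1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + gg1;
    g0 /= s; gg1 /= s;
    if (t == 0) { g1[0] = g0; g1[1] = gg1; }
    N0 += g0; N1 += gg1;
    sx0 += g0 * x[t]; sx1 += gg1 * x[t];
    sxx0 += g0 * x[t] * x[t]; sxx1 += gg1 * x[t] * x[t];
    if (t < T - 1) {
      double denom = 0.0;
      double xv[4];
      int idx = 0;
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j) {
          double v = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j);
          xv[idx++] = v;
          denom += v;
        }
      idx = 0;
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j)
          xi(i, j) += xv[idx++] / denom;
    }
  }
  return List::create(_["loglik"] = loglik,
                      _["N"] = NumericVector::create(N0, N1),
                      _["sum_x"] = NumericVector::create(sx0, sx1),
                      _["sum_xx"] = NumericVector::create(sxx0, sxx1),
                      _["xi"] = xi, _["gamma1"] = g1);
}

// Viterbi most-probable path for the 2-state Gaussian HMM (1-based states).
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericVector x, NumericVector mu,
                              NumericVector sigma, NumericMatrix A,
                              NumericVector pi0) {
  int T = x.size();
  NumericMatrix delta(T, 2);
  IntegerMatrix psi(T, 2);
  NumericMatrix logA(2, 2);
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      logA(i, j) = std::log(A(i, j) + 1e-300);
  for (int j = 0; j < 2; ++j)
    delta(0, j) = std::log(pi0[j] + 1e-300) +
                  std::log(dnorm_c(x[0], mu[j], sigma[j]) + 1e-300);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < 2; ++j) {
      double v0 = delta(t - 1, 0) + logA(0, j);
      double v1 = delta(t - 1, 1) + logA(1, j);
      if (v0 >= v1) { delta(t, j) = v0; psi(t, j) = 0; }
      else { delta(t, j) = v1; psi(t, j) = 1; }
      delta(t, j) += std::log(dnorm_c(x[t], mu[j], sigma[j]) + 1e-300);
    }
  IntegerVector path(T);
  int cur = (delta(T - 1, 0) >= delta(T - 1, 1)) ? 0 : 1;
  path[T - 1] = cur + 1;
  for (int t = T - 2; t >= 0; --t) {
    cur = psi(t + 1, cur);
    path[t] = cur + 1;
  }
  return path;
}
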