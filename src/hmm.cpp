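// Gaussian-emission hidden Markov model core: scaled forward/backward,
// Baum-Welch EM, and Viterbi decoding. Kept in C++ because per-trace fits
// with multiple restarts across a range of state counts dominate pipeline
// runtime.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gauss_pdf(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  double d = std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
  return d > 1e-300 ? d : 1e-300;
}

// One scaled forward-backward pass. Returns loglik, gamma (T x K) and
// summed xi (K x K).
static double forward_backward(const NumericVector& x,
                               const NumericVector& mu,
                               const NumericVector& sd,
                               const NumericMatrix& A,
                               const NumericVector& pi,
                               NumericMatrix& gamma,
                               NumericMatrix& xi_sum) {
  const int T = x.size(), K = mu.size();
  NumericMatrix B(T, K), alpha(T, K), beta(T, K);
  NumericVector c(T);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = gauss_pdf(x[t], mu[k], sd[k]);

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  c[0] = s > 0 ? s : 1e-300;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c[0];
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    c[t] = s > 0 ? s : 1e-300;
    for (int k = 0; k < K; ++k) alpha(t, k) /= c[t];
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t)
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g > 0) for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  std::fill(xi_sum.begin(), xi_sum.end(), 0.0);
  for (int t = 0; t < T - 1; ++t) {
    double denom = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        denom += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
    if (denom <= 0) continue;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / denom;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]);
  return ll;
}

// [[Rcpp::export(name = ".hmm_loglik")]]
double hmm_loglik(NumericVector x, NumericVector mu, NumericVector sd,
                  NumericMatrix A, NumericVector pi) {
  const int T = x.size(), K = mu.size();
  NumericMatrix gamma(T, K), xi(K, K);
  return forward_backward(x, mu, sd, A, pi, gamma, xi);
}

// [[Rcpp::export(name = ".hmm_baum_welch")]]
List hmm_baum_welch(NumericVector x, NumericVector mu0, NumericVector sd0,
                    NumericMatrix A0, NumericVector pi0,
                    int max_iter, double tol, double sd_floor) {
  const int T = x.size(), K = mu0.size();
  NumericVector mu = clone(mu0), sd = clone(sd0), pi = clone(pi0);
  NumericMatrix A = clone(A0);
  NumericMatrix gamma(T, K), xi(K, K);
  double ll = R_NegInf, ll_prev = R_NegInf;
  bool floored = false, converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    ll = forward_backward(x, mu, sd, A, pi, gamma, xi);
    if (it > 0 && std::fabs(ll - ll_prev) < tol) { converged = true; break; }
    ll_prev = ll;
    // M-step
    for (int k = 0; k < K; ++k) {
      double w = 0.0, wx = 0.0;
      for (int t = 0; t < T; ++t) { w += gamma(t, k); wx += gamma(t, k) * x[t]; }
      if (w > 1e-12) mu[k] = wx / w;
      double wv = 0.0;
      for (int t = 0; t < T; ++t) {
        double d = x[t] - mu[k];
        wv += gamma(t, k) * d * d;
      }
      double v = (w > 1e-12) ? wv / w : sd[k] * sd[k];
      if (v < sd_floor * sd_floor) { v = sd_floor * sd_floor; floored = true; }
      sd[k] = std::sqrt(v);
      pi[k] = gamma(0, k);
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += xi(k, j);
      for (int j = 0; j < K; ++j)
        A(k, j) = rs > 1e-12 ? xi(k, j) / rs : (j == k ? 1.0 : 0.0);
    }
  }
  if (!converged)   // refresh ll so it matches the returned parameters
    ll = forward_backward(x, mu, sd, A, pi, gamma, xi);
  return List::create(_["means"] = mu, _["sds"] = sd,
                      _["transition"] = A, _["initial"] = pi,
                      _["log_likelihood"] = ll, _["iterations"] = it,
                      _["converged"] = converged, _["variance_floored"] = floored);
}

// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu, NumericVector sd,
                          NumericMatrix A, NumericVector pi) {
  const int T = x.size(), K = mu.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k)
    delta(0, k) = std::log(pi[k] > 1e-300 ? pi[k] : 1e-300) +
      std::log(gauss_pdf(x[0], mu[k], sd[k]));
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = delta(t - 1, j) +
          std::log(A(j, k) > 1e-300 ? A(j, k) : 1e-300);
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + std::log(gauss_pdf(x[t], mu[k], sd[k]));
      psi(t, k) = arg;
    }
  IntegerVector path(T);
  double best = R_NegInf;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); path[T - 1] = k; }
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; ++t) path[t] += 1;   // 1-based for R
  return path;
}
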