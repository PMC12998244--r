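#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Log-density of N(x; mu, var).
static inline double ldnorm(double x, double mu, double var) {
  double d = x - mu;
  return -0.5 * (std::log(2.0 * M_PI * var) + d * d / var);
}

static inline double logsumexp2(double a, double b) {
  double m = a > b ? a : b;
  if (!std::isfinite(m)) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Exact forward-algorithm marginal log-likelihood log p(x | model), computed
// in log space so contours of ~1e5 frames do not underflow. Generic in the
// number of states.
// [[Rcpp::export]]
double cpp_forward_loglik(NumericVector x, NumericVector pi,
                          NumericMatrix A, NumericVector mu,
                          NumericVector var) {
  const int K = pi.size(), T = x.size();
  if (T == 0) stop("empty observation sequence");
  std::vector<double> la(K), lb(K);
  std::vector<double> logA(K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      logA[i * K + j] = std::log(A(i, j));
  for (int s = 0; s < K; ++s)
    la[s] = std::log(pi[s]) + ldnorm(x[0], mu[s], var[s]);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < K; ++s) {
      double acc = R_NegInf;
      for (int r = 0; r < K; ++r)
        acc = logsumexp2(acc, la[r] + logA[r * K + s]);
      lb[s] = acc + ldnorm(x[t], mu[s], var[s]);
    }
    la = lb;
  }
  double out = R_NegInf;
  for (int s = 0; s < K; ++s) out = logsumexp2(out, la[s]);
  return out;
}

// One Baum-Welch EM run over multiple independent sequences, scaled
// forward-backward. Returns fitted parameters and the per-iteration total
// log-likelihood trace (log-lik of the parameters *entering* each E-step,
// so the trace is non-decreasing for a correct implementation).
// [[Rcpp::export]]
List cpp_baum_welch(List seqs, NumericVector pi0, NumericMatrix A0,
                    NumericVector mu0, NumericVector var0,
                    int maxIter, double tol, double varFloor) {
  const int K = pi0.size();
  const int S = seqs.size();
  std::vector<NumericVector> xs;
  xs.reserve(S);
  long totalFrames = 0;
  for (int s = 0; s < S; ++s) {
    NumericVector v = seqs[s];
    if (v.size() > 0) { xs.push_back(v); totalFrames += v.size(); }
  }
  if (xs.empty()) stop("all observation sequences are empty");

  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> A(K * K), mu(mu0.begin(), mu0.end()),
      var(var0.begin(), var0.end());
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A[i * K + j] = A0(i, j);
  for (int s = 0; s < K; ++s) if (var[s] < varFloor) var[s] = varFloor;

  std::vector<double> llTrace;
  double prevLL = R_NegInf;

  for (int iter = 0; iter < maxIter; ++iter) {
    // accumulators
    std::vector<double> piAcc(K, 0.0), xiAcc(K * K, 0.0),
        gAcc(K, 0.0), gxAcc(K, 0.0), gTransAcc(K, 0.0);
    std::vector<double> gxxAcc(K, 0.0);
    double ll = 0.0;

    for (size_t q = 0; q < xs.size(); ++q) {
      const NumericVector &x = xs[q];
      const int T = x.size();
      std::vector<double> alpha(T * K), beta(T * K), b(T * K), c(T);
      for (int t = 0; t < T; ++t)
        for (int s = 0; s < K; ++s)
          b[t * K + s] = std::exp(ldnorm(x[t], mu[s], var[s])) + 1e-300;
      // forward, scaled
      double cs = 0.0;
      for (int s = 0; s < K; ++s) {
        alpha[s] = pi[s] * b[s];
        cs += alpha[s];
      }
      c[0] = cs;
      for (int s = 0; s < K; ++s) alpha[s] /= cs;
      for (int t = 1; t < T; ++t) {
        cs = 0.0;
        for (int s = 0; s < K; ++s) {
          double a = 0.0;
          for (int r = 0; r < K; ++r)
            a += alpha[(t - 1) * K + r] * A[r * K + s];
          a *= b[t * K + s];
          alpha[t * K + s] = a;
          cs += a;
        }
        c[t] = cs;
        for (int s = 0; s < K; ++s) alpha[t * K + s] /= cs;
      }
      for (int t = 0; t < T; ++t) ll += std::log(c[t]);
      // backward, scaled
      for (int s = 0; s < K; ++s) beta[(T - 1) * K + s] = 1.0;
      for (int t = T - 2; t >= 0; --t)
        for (int s = 0; s < K; ++s) {
          double a = 0.0;
          for (int r = 0; r < K; ++r)
            a += A[s * K + r] * b[(t + 1) * K + r] * beta[(t + 1) * K + r];
          beta[t * K + s] = a / c[t + 1];
        }
      // gamma & xi accumulation
      for (int t = 0; t < T; ++t) {
        for (int s = 0; s < K; ++s) {
          double g = alpha[t * K + s] * beta[t * K + s];
          gAcc[s] += g;
          gxAcc[s] += g * x[t];
          gxxAcc[s] += g * x[t] * x[t];
          if (t == 0) piAcc[s] += g;
          if (t < T - 1) gTransAcc[s] += g;
        }
      }
      for (int t = 0; t < T - 1; ++t)
        for (int i = 0; i < K; ++i)
          for (int j = 0; j < K; ++j)
            xiAcc[i * K + j] += alpha[t * K + i] * A[i * K + j] *
              b[(t + 1) * K + j] * beta[(t + 1) * K + j] / c[t + 1];
    }

    llTrace.push_back(ll);
    bool converged = std::isfinite(prevLL) &&
      (ll - prevLL) <= tol * (std::fabs(prevLL) + 1e-12);
    prevLL = ll;

    // M-step
    double piTot = 0.0;
    for (int s = 0; s < K; ++s) piTot += piAcc[s];
    for (int s = 0; s < K; ++s) pi[s] = piAcc[s] / piTot;
    for (int i = 0; i < K; ++i) {
      double rowTot = gTransAcc[i];
      if (rowTot > 0) {
        for (int j = 0; j < K; ++j) A[i * K + j] = xiAcc[i * K + j] / rowTot;
        // renormalise against accumulated rounding
        double rs = 0.0;
        for (int j = 0; j < K; ++j) rs += A[i * K + j];
        for (int j = 0; j < K; ++j) A[i * K + j] /= rs;
      }
    }
    for (int s = 0; s < K; ++s) {
      if (gAcc[s] > 0) {
        mu[s] = gxAcc[s] / gAcc[s];
        double v = gxxAcc[s] / gAcc[s] - mu[s] * mu[s];
        var[s] = v > varFloor ? v : varFloor;
      }
    }
    if (converged) break;
  }

  NumericMatrix Aout(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Aout(i, j) = A[i * K + j];
  return List::create(
    _["initialProbs"] = NumericVector(pi.begin(), pi.end()),
    _["transitions"] = Aout,
    _["emissionMeans"] = NumericVector(mu.begin(), mu.end()),
    _["emissionVars"] = NumericVector(var.begin(), var.end()),
    _["logLikTrace"] = NumericVector(llTrace.begin(), llTrace.end()),
    _["logLik"] = llTrace.back());
}
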