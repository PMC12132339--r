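#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a discrete-time HMM.
// logB: T x K emission log-densities; pi: K initial probs; A: K x K.
// Returns loglik, gamma (T x K posteriors), xi (K x K summed transition
// posteriors) and the scaled forward variables.
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logB, NumericVector pi,
                          NumericMatrix A) {
  int T = logB.nrow(), K = logB.ncol();
  NumericMatrix B(T, K);
  NumericVector m(T);
  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > mx) mx = logB(t, k);
    m[t] = mx;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - mx);
  }
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  if (s <= 0) s = 1e-300;
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0) s = 1e-300;
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    if (g <= 0) g = 1e-300;
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    if (t < T - 1) {
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          xi(i, j) += alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];
    }
  }
  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + m[t];
  return List::create(_["loglik"] = ll, _["gamma"] = gamma, _["xi"] = xi);
}

// Viterbi decoding in log domain; returns 1-based state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericVector pi,
                          NumericMatrix A) {
  int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  const double NEG = -1e300;
  for (int k = 0; k < K; ++k)
    delta(0, k) = (pi[k] > 0 ? std::log(pi[k]) : NEG) + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = NEG; int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + (A(i, j) > 0 ? std::log(A(i, j)) : NEG);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = NEG; int arg = 0;
  for (int k = 0; k < K; ++k) if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
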