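#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over one contiguous observed segment.
// B is K x T with per-bin emission probabilities; columns may carry an
// arbitrary positive rescaling (the caller adds the log of that factor
// back into the log-likelihood). Returns the scaled log-likelihood,
// posterior state marginals (gamma), the summed transition posteriors
// (xi_sum) and the first-column posterior used for initial-probability
// updates.
// [[Rcpp::export(name = ".hmm_forward_backward")]]
List hmm_forward_backward(NumericMatrix B, NumericVector init,
                          NumericMatrix A) {
  const int K = B.nrow(), T = B.ncol();
  NumericMatrix alpha(K, T), beta(K, T), gamma(K, T);
  NumericVector c(T);
  double loglik = 0.0;

  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(k, 0) = init[k] * B(k, 0);
    s += alpha(k, 0);
  }
  if (s <= 0.0) stop("forward: zero total probability at t=1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(k, 0) /= s;
  loglik += std::log(s);

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(i, t - 1) * A(i, j);
      a *= B(j, t);
      alpha(j, t) = a;
      s += a;
    }
    if (s <= 0.0) stop("forward: zero total probability");
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(j, t) /= s;
    loglik += std::log(s);
  }

  for (int k = 0; k < K; ++k) beta(k, T - 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += A(i, j) * B(j, t + 1) * beta(j, t + 1);
      beta(i, t) = b / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(k, t) = alpha(k, t) * beta(k, t);
      g += gamma(k, t);
    }
    for (int k = 0; k < K; ++k) gamma(k, t) /= g;
  }

  NumericMatrix xi_sum(K, K);
  for (int t = 0; t + 1 < T; ++t) {
    for (int i = 0; i < K; ++i) {
      const double ai = alpha(i, t);
      for (int j = 0; j < K; ++j)
        xi_sum(i, j) += ai * A(i, j) * B(j, t + 1) * beta(j, t + 1) /
                        c[t + 1];
    }
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum,
                      _["gamma1"] = gamma(_, 0));
}

// Log-space Viterbi over one contiguous observed segment; ties broken
// toward the lowest state index (strict improvement required to switch).
// Returns 1-based state indices.
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(NumericMatrix logB, NumericVector logInit,
                          NumericMatrix logA) {
  const int K = logB.nrow(), T = logB.ncol();
  NumericMatrix delta(K, T);
  IntegerMatrix psi(K, T);
  for (int k = 0; k < K; ++k) delta(k, 0) = logInit[k] + logB(k, 0);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(0, t - 1) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        const double v = delta(i, t - 1) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(j, t) = best + logB(j, t);
      psi(j, t) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = delta(0, T - 1);
  for (int k = 1; k < K; ++k)
    if (delta(k, T - 1) > best) { best = delta(k, T - 1); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(arg, t + 1);
    path[t] = arg + 1;
  }
  return path;
}
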