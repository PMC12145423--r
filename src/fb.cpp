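#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for one chain.
//
// logb: T x k matrix of per-position log observation likelihoods
// init: length-k initial distribution
// trans: k x k row-stochastic transition matrix
//
// Returns posterior state probabilities (gamma, T x k), summed expected
// transition counts (xi, k x k), and the chain log-likelihood. Per-position
// scaling keeps everything in double range; the scaling constants plus the
// row-max shifts of logb reconstruct the log-likelihood exactly.
// [[Rcpp::export(name = ".fb_chain")]]
List fb_chain(NumericMatrix logb, NumericVector init, NumericMatrix trans) {
  const int T = logb.nrow(), k = logb.ncol();
  NumericMatrix b(T, k);          // shifted emission likelihoods
  NumericVector shift(T);
  for (int t = 0; t < T; ++t) {
    double m = logb(t, 0);
    for (int j = 1; j < k; ++j) if (logb(t, j) > m) m = logb(t, j);
    shift[t] = m;
    for (int j = 0; j < k; ++j) b(t, j) = std::exp(logb(t, j) - m);
  }

  NumericMatrix alpha(T, k);
  NumericVector c(T);
  double ll = 0.0;

  // forward
  double s = 0.0;
  for (int j = 0; j < k; ++j) { alpha(0, j) = init[j] * b(0, j); s += alpha(0, j); }
  c[0] = s;
  for (int j = 0; j < k; ++j) alpha(0, j) /= s;
  ll += std::log(s) + shift[0];
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < k; ++j) {
      double a = 0.0;
      for (int i = 0; i < k; ++i) a += alpha(t - 1, i) * trans(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      s += a;
    }
    c[t] = s;
    for (int j = 0; j < k; ++j) alpha(t, j) /= s;
    ll += std::log(s) + shift[t];
  }

  // backward + posteriors + expected transition counts
  NumericMatrix gamma(T, k), xi(k, k);
  std::vector<double> beta(k, 1.0), beta_next(k);
  for (int j = 0; j < k; ++j) gamma(T - 1, j) = alpha(T - 1, j);
  for (int t = T - 2; t >= 0; --t) {
    // w_j = b_{t+1,j} * beta_{t+1,j} / c_{t+1}
    std::vector<double> w(k);
    for (int j = 0; j < k; ++j) w[j] = b(t + 1, j) * beta[j] / c[t + 1];
    for (int i = 0; i < k; ++i) {
      double bi = 0.0;
      for (int j = 0; j < k; ++j) {
        double x = alpha(t, i) * trans(i, j) * w[j];
        xi(i, j) += x;
        bi += trans(i, j) * w[j];
      }
      beta_next[i] = bi;
      gamma(t, i) = alpha(t, i) * bi;
    }
    beta.swap(beta_next);
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// Per-position argmax of the posterior with smallest-index tie-break.
// [[Rcpp::export(name = ".argmax_rows")]]
IntegerVector argmax_rows(NumericMatrix x) {
  const int n = x.nrow(), k = x.ncol();
  IntegerVector out(n);
  for (int t = 0; t < n; ++t) {
    int best = 0;
    for (int j = 1; j < k; ++j) if (x(t, j) > x(t, best)) best = j;
    out[t] = best + 1;
  }
  return out;
}
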