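#include <Rcpp.h>
using namespace Rcpp;

// Batched Poisson-IRLS across bins sharing one design matrix.
//
// X: n_tracks x q design (intercept first), Y: n_bins x n_tracks counts.
// Fits, for every bin, a log-link Poisson regression of the bin's track
// counts on X (quasi-Poisson point estimates coincide). Returns the
// coefficient matrix (n_bins x q) and a convergence flag per bin.
// [[Rcpp::export(name = ".irls_poisson_batch")]]
List irls_poisson_batch(NumericMatrix X, NumericMatrix Y,
                        int max_iter, double tol) {
  const int n = X.nrow(), q = X.ncol(), B = Y.nrow();
  NumericMatrix beta(B, q);
  LogicalVector converged(B);
  std::vector<double> eta(n), mu(n), A(q * q), b(q), sol(q);

  for (int bin = 0; bin < B; ++bin) {
    // start at the intercept-only fit
    double ybar = 0.0;
    for (int d = 0; d < n; ++d) ybar += Y(bin, d);
    ybar /= n;
    std::vector<double> coef(q, 0.0);
    coef[0] = std::log(ybar > 0 ? ybar : 1e-8);
    double dev_old = R_PosInf;
    bool ok = false;

    for (int it = 0; it < max_iter; ++it) {
      for (int d = 0; d < n; ++d) {
        double e = 0.0;
        for (int j = 0; j < q; ++j) e += X(d, j) * coef[j];
        if (e > 30.0) e = 30.0;
        if (e < -30.0) e = -30.0;
        eta[d] = e;
        mu[d] = std::exp(e);
      }
      // weighted normal equations: A = X'WX, b = X'W z, W = mu,
      // z = eta + (y - mu)/mu
      std::fill(A.begin(), A.end(), 0.0);
      std::fill(b.begin(), b.end(), 0.0);
      for (int d = 0; d < n; ++d) {
        const double w = mu[d];
        const double z = eta[d] + (Y(bin, d) - mu[d]) / mu[d];
        for (int i = 0; i < q; ++i) {
          const double xwi = X(d, i) * w;
          b[i] += xwi * z;
          for (int j = i; j < q; ++j) A[i * q + j] += xwi * X(d, j);
        }
      }
      for (int i = 0; i < q; ++i)
        for (int j = 0; j < i; ++j) A[i * q + j] = A[j * q + i];
      // Gaussian elimination with partial pivoting
      bool singular = false;
      std::vector<double> M(A);
      std::copy(b.begin(), b.end(), sol.begin());
      for (int col = 0; col < q && !singular; ++col) {
        int piv = col;
        for (int r = col + 1; r < q; ++r)
          if (std::fabs(M[r * q + col]) > std::fabs(M[piv * q + col])) piv = r;
        if (std::fabs(M[piv * q + col]) < 1e-12) { singular = true; break; }
        if (piv != col) {
          for (int c2 = 0; c2 < q; ++c2) std::swap(M[col * q + c2], M[piv * q + c2]);
          std::swap(sol[col], sol[piv]);
        }
        for (int r = col + 1; r < q; ++r) {
          const double f = M[r * q + col] / M[col * q + col];
          for (int c2 = col; c2 < q; ++c2) M[r * q + c2] -= f * M[col * q + c2];
          sol[r] -= f * sol[col];
        }
      }
      if (singular) break;
      for (int r = q - 1; r >= 0; --r) {
        double s = sol[r];
        for (int c2 = r + 1; c2 < q; ++c2) s -= M[r * q + c2] * coef[c2];
        coef[r] = s / M[r * q + r];
      }
      // deviance for the convergence check
      double dev = 0.0;
      for (int d = 0; d < n; ++d) {
        double e = 0.0;
        for (int j = 0; j < q; ++j) e += X(d, j) * coef[j];
        if (e > 30.0) e = 30.0;
        if (e < -30.0) e = -30.0;
        const double m = std::exp(e);
        const double y = Y(bin, d);
        dev += 2.0 * ((y > 0 ? y * std::log(y / m) : 0.0) - (y - m));
      }
      if (std::isfinite(dev) &&
          std::fabs(dev - dev_old) < tol * (std::fabs(dev) + 0.1)) {
        ok = true;
        break;
      }
      dev_old = dev;
    }
    converged[bin] = ok;
    for (int j = 0; j < q; ++j) beta(bin, j) = ok ? coef[j] : NA_REAL;
  }
  return List::create(_["beta"] = beta, _["converged"] = converged);
}
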