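#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward E-step for a 2-state Gaussian-emission HMM over a
// series split into independent segments (stitch seams = segment boundaries;
// no transition is accumulated across a seam).
//
// Returns the total log-likelihood plus the sufficient statistics needed for
// the M-step: per-state responsibilities summed (Ng), responsibility-weighted
// sums of e and e^2 (Sx, Sxx), expected transition counts (Xi, 2x2), and the
// summed state-1 responsibilities at segment starts (Pi0).

static const double INV_SQRT_2PI = 0.3989422804014327;

static inline double dens(double x, double mu, double sigma) {
  double z = (x - mu) / sigma;
  double b = INV_SQRT_2PI / sigma * std::exp(-0.5 * z * z);
  return b < 1e-300 ? 1e-300 : b;
}

// [[Rcpp::export]]
List hmm2_estep_cpp(NumericVector e, IntegerVector seglen,
                    NumericVector mu, NumericVector sigma,
                    NumericMatrix A, NumericVector pi0) {
  int nseg = seglen.size();
  double loglik = 0.0;
  NumericVector Ng(2), Sx(2), Sxx(2), Pi(2);
  NumericMatrix Xi(2, 2);
  int off = 0;
  for (int s = 0; s < nseg; ++s) {
    int T = seglen[s];
    NumericMatrix alpha(T, 2), beta(T, 2), B(T, 2);
    NumericVector c(T);
    for (int t = 0; t < T; ++t) {
      B(t, 0) = dens(e[off + t], mu[0], sigma[0]);
      B(t, 1) = dens(e[off + t], mu[1], sigma[1]);
    }
    // forward with scaling
    alpha(0, 0) = pi0[0] * B(0, 0);
    alpha(0, 1) = pi0[1] * B(0, 1);
    c[0] = alpha(0, 0) + alpha(0, 1);
    alpha(0, 0) /= c[0]; alpha(0, 1) /= c[0];
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < 2; ++j)
        alpha(t, j) = (alpha(t - 1, 0) * A(0, j) + alpha(t - 1, 1) * A(1, j)) * B(t, j);
      c[t] = alpha(t, 0) + alpha(t, 1);
      if (c[t] <= 0.0) stop("non-finite likelihood in forward pass");
      alpha(t, 0) /= c[t]; alpha(t, 1) /= c[t];
    }
    // backward with the same scaling
    beta(T - 1, 0) = 1.0; beta(T - 1, 1) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int i = 0; i < 2; ++i)
        beta(t, i) = (A(i, 0) * B(t + 1, 0) * beta(t + 1, 0) +
                      A(i, 1) * B(t + 1, 1) * beta(t + 1, 1)) / c[t + 1];
    }
    // accumulate
    for (int t = 0; t < T; ++t) {
      double g0 = alpha(t, 0) * beta(t, 0);
      double g1 = alpha(t, 1) * beta(t, 1);
      double gs = g0 + g1;
      g0 /= gs; g1 /= gs;
      Ng[0] += g0; Ng[1] += g1;
      Sx[0] += g0 * e[off + t]; Sx[1] += g1 * e[off + t];
      Sxx[0] += g0 * e[off + t] * e[off + t];
      Sxx[1] += g1 * e[off + t] * e[off + t];
      if (t == 0) { Pi[0] += g0; Pi[1] += g1; }
    }
    for (int t = 0; t < T - 1; ++t) {
      double denom = 0.0;
      double x[2][2];
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j) {
          x[i][j] = alpha(t, i) * A(i, j) * B(t + 1, j) * beta(t + 1, j) / c[t + 1];
          denom += x[i][j];
        }
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j)
          Xi(i, j) += x[i][j] / denom;
    }
    for (int t = 0; t < T; ++t) loglik += std::log(c[t]);
    off += T;
  }
  return List::create(_["loglik"] = loglik, _["Ng"] = Ng, _["Sx"] = Sx,
                      _["Sxx"] = Sxx, _["Xi"] = Xi, _["Pi"] = Pi,
                      _["nseg"] = nseg);
}

// Viterbi decoding per segment; ties in the backpointer are broken toward
// staying in the same state (hysteresis). Returns 1-based states.
// [[Rcpp::export]]
IntegerVector hmm2_viterbi_cpp(NumericVector e, IntegerVector seglen,
                               NumericVector mu, NumericVector sigma,
                               NumericMatrix A, NumericVector pi0) {
  int n = e.size();
  IntegerVector path(n);
  int off = 0;
  double lA[2][2], lpi[2];
  for (int i = 0; i < 2; ++i) {
    lpi[i] = std::log(pi0[i] > 0 ? pi0[i] : 1e-300);
    for (int j = 0; j < 2; ++j)
      lA[i][j] = std::log(A(i, j) > 0 ? A(i, j) : 1e-300);
  }
  for (int s = 0; s < seglen.size(); ++s) {
    int T = seglen[s];
    NumericMatrix d(T, 2);
    IntegerMatrix psi(T, 2);
    for (int k = 0; k < 2; ++k)
      d(0, k) = lpi[k] + std::log(dens(e[off], mu[k], sigma[k]));
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < 2; ++j) {
        double lb = std::log(dens(e[off + t], mu[j], sigma[j]));
        double s0 = d(t - 1, 0) + lA[0][j];
        double s1 = d(t - 1, 1) + lA[1][j];
        int arg;
        if (s0 == s1) arg = j;            // tie: prefer no transition
        else arg = (s0 > s1) ? 0 : 1;
        d(t, j) = (arg == 0 ? s0 : s1) + lb;
        psi(t, j) = arg;
      }
    }
    int st = (d(T - 1, 0) >= d(T - 1, 1)) ? 0 : 1;
    path[off + T - 1] = st + 1;
    for (int t = T - 2; t >= 0; --t) {
      st = psi(t + 1, st);
      path[off + t] = st + 1;
    }
    off += T;
  }
  return path;
}
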