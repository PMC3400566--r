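#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a 2-state Gaussian HMM over concatenated
// segments (chromosomes). Transitions are reset at segment boundaries:
// each segment starts from the initial distribution.
//
// Returns per-position posterior state probabilities (gamma), summed
// expected transition counts (xi, pooled over segments), the summed
// posterior at segment starts (for the initial-distribution update) and
// the total log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector x, IntegerVector seg_lengths,
                          NumericVector mu, NumericVector sd,
                          NumericMatrix trans, NumericVector init) {
  const int T = x.size();
  NumericMatrix gamma(T, 2);
  NumericMatrix xi(2, 2);
  NumericVector init_post(2);
  double loglik = 0.0;

  NumericMatrix b(T, 2);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < 2; ++k)
      b(t, k) = R::dnorm(x[t], mu[k], sd[k], 0) + 1e-300;

  NumericMatrix alpha(T, 2), beta(T, 2);
  NumericVector cvec(T);

  int offset = 0;
  for (int s = 0; s < seg_lengths.size(); ++s) {
    const int L = seg_lengths[s];
    // forward (scaled)
    double c0 = 0.0;
    for (int k = 0; k < 2; ++k) {
      alpha(offset, k) = init[k] * b(offset, k);
      c0 += alpha(offset, k);
    }
    for (int k = 0; k < 2; ++k) alpha(offset, k) /= c0;
    cvec[offset] = c0;
    for (int t = 1; t < L; ++t) {
      const int i = offset + t;
      double ct = 0.0;
      for (int k = 0; k < 2; ++k) {
        double a = alpha(i - 1, 0) * trans(0, k) +
                   alpha(i - 1, 1) * trans(1, k);
        alpha(i, k) = a * b(i, k);
        ct += alpha(i, k);
      }
      for (int k = 0; k < 2; ++k) alpha(i, k) /= ct;
      cvec[i] = ct;
    }
    // backward (scaled)
    for (int k = 0; k < 2; ++k) beta(offset + L - 1, k) = 1.0;
    for (int t = L - 2; t >= 0; --t) {
      const int i = offset + t;
      for (int k = 0; k < 2; ++k) {
        double v = 0.0;
        for (int j = 0; j < 2; ++j)
          v += trans(k, j) * b(i + 1, j) * beta(i + 1, j);
        beta(i, k) = v / cvec[i + 1];
      }
    }
    // posteriors
    for (int t = 0; t < L; ++t) {
      const int i = offset + t;
      double norm = 0.0;
      for (int k = 0; k < 2; ++k) {
        gamma(i, k) = alpha(i, k) * beta(i, k);
        norm += gamma(i, k);
      }
      for (int k = 0; k < 2; ++k) gamma(i, k) /= norm;
    }
    for (int k = 0; k < 2; ++k) init_post[k] += gamma(offset, k);
    // expected transition counts
    for (int t = 1; t < L; ++t) {
      const int i = offset + t;
      double tmp[2][2];
      double denom = 0.0;
      for (int k = 0; k < 2; ++k)
        for (int j = 0; j < 2; ++j) {
          tmp[k][j] = alpha(i - 1, k) * trans(k, j) * b(i, j) * beta(i, j);
          denom += tmp[k][j];
        }
      for (int k = 0; k < 2; ++k)
        for (int j = 0; j < 2; ++j)
          xi(k, j) += tmp[k][j] / denom;
    }
    for (int t = 0; t < L; ++t) loglik += std::log(cvec[offset + t]);
    offset += L;
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["init_post"] = init_post, _["loglik"] = loglik);
}
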