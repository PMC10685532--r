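#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// Token n in document d with word w is reassigned by sampling from the
// standard collapsed conditional
//   p(z_n = t | z_-n, w) ~ (n_{d,t} + alpha) (n_{t,w} + beta) / (n_t + V beta).
// phi and theta are point-estimated from the smoothed counts, averaged over
// every post-burn-in sweep. Randomness comes from R's RNG so results are
// reproducible from set.seed() on the R side.
//
// doc_id / word_id are 0-based token streams; the per-sweep log-likelihood
// sum_n log(sum_t theta_dt phi_tw) is returned as a convergence trace.

// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc_id, IntegerVector word_id,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double beta, int n_iter, int burn_in) {
  const int N = doc_id.size();
  const int D = n_docs, V = n_vocab, K = n_topics;

  IntegerMatrix ndk(D, K), nkw(K, V);
  IntegerVector nk(K), nd(D), z(N);

  // random initial assignments
  for (int n = 0; n < N; ++n) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[n] = k;
    ndk(doc_id[n], k)++;
    nkw(k, word_id[n])++;
    nk[k]++;
    nd[doc_id[n]]++;
  }

  NumericMatrix phi_sum(K, V), theta_sum(D, K);
  NumericVector ll(n_iter);
  int n_samples = 0;
  std::vector<double> p(K);

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int n = 0; n < N; ++n) {
      const int d = doc_id[n], w = word_id[n];
      int k = z[n];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;

      double tot = 0.0;
      for (int t = 0; t < K; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nkw(t, w) + beta) / (nk[t] + V * beta);
        tot += p[t];
      }
      double u = unif_rand() * tot;
      double acc = 0.0;
      k = K - 1;
      for (int t = 0; t < K; ++t) {
        acc += p[t];
        if (u <= acc) { k = t; break; }
      }
      z[n] = k;
      ndk(d, k)++; nkw(k, w)++; nk[k]++;
    }

    // token log-likelihood under the current count-based estimates
    double l = 0.0;
    for (int n = 0; n < N; ++n) {
      const int d = doc_id[n], w = word_id[n];
      double pw = 0.0;
      for (int t = 0; t < K; ++t) {
        double theta = (ndk(d, t) + alpha) / (nd[d] + K * alpha);
        double phi = (nkw(t, w) + beta) / (nk[t] + V * beta);
        pw += theta * phi;
      }
      l += std::log(pw);
    }
    ll[iter] = l;

    if (iter >= burn_in) {
      for (int t = 0; t < K; ++t)
        for (int w = 0; w < V; ++w)
          phi_sum(t, w) += (nkw(t, w) + beta) / (nk[t] + V * beta);
      for (int d = 0; d < D; ++d)
        for (int t = 0; t < K; ++t)
          theta_sum(d, t) += (ndk(d, t) + alpha) / (nd[d] + K * alpha);
      n_samples++;
    }
  }

  NumericMatrix phi(K, V), theta(D, K);
  for (int t = 0; t < K; ++t)
    for (int w = 0; w < V; ++w)
      phi(t, w) = phi_sum(t, w) / n_samples;
  for (int d = 0; d < D; ++d)
    for (int t = 0; t < K; ++t)
      theta(d, t) = theta_sum(d, t) / n_samples;

  return List::create(_["phi"] = phi, _["theta"] = theta,
                      _["assignments"] = z,
                      _["log_likelihood"] = ll,
                      _["n_samples"] = n_samples);
}
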