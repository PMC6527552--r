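#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA over a token stream given as sparse
// triplets (cell, gene, count). Uses R's RNG, so results are reproducible
// from set.seed() on the R side. Parameter estimates come either from the
// final sweep's assignment counts or from an average of post-burn-in
// sweeps.
//
// cell/gene are 0-based; counts expanded token-by-token in triplet order.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector cell, IntegerVector gene,
                   IntegerVector count, int n_cells, int n_genes,
                   int n_topics, double alpha, double beta,
                   int n_iter, int burn_in, bool average) {
  const int K = n_topics, V = n_genes, D = n_cells;
  long n_tokens = 0;
  for (int e = 0; e < count.size(); ++e) n_tokens += count[e];
  if (n_tokens == 0) stop("zero total tokens");

  std::vector<int> tok_d(n_tokens), tok_w(n_tokens), z(n_tokens);
  {
    long t = 0;
    for (int e = 0; e < count.size(); ++e)
      for (int c = 0; c < count[e]; ++c) {
        tok_d[t] = cell[e];
        tok_w[t] = gene[e];
        ++t;
      }
  }

  std::vector<int> n_dt((size_t)D * K, 0), n_tw((size_t)K * V, 0),
      n_t(K, 0), n_d(D, 0);
  for (long t = 0; t < n_tokens; ++t) {
    int k = (int)(unif_rand() * K);
    if (k == K) k = K - 1;
    z[t] = k;
    n_dt[(size_t)tok_d[t] * K + k]++;
    n_tw[(size_t)k * V + tok_w[t]]++;
    n_t[k]++;
    n_d[tok_d[t]]++;
  }

  std::vector<double> p(K);
  std::vector<double> acc_dt, acc_tw, acc_t;
  int n_acc = 0;
  if (average) {
    acc_dt.assign((size_t)D * K, 0.0);
    acc_tw.assign((size_t)K * V, 0.0);
    acc_t.assign(K, 0.0);
  }
  const double Vbeta = V * beta;

  for (int it = 0; it < n_iter; ++it) {
    for (long t = 0; t < n_tokens; ++t) {
      const int d = tok_d[t], w = tok_w[t], old = z[t];
      n_dt[(size_t)d * K + old]--;
      n_tw[(size_t)old * V + w]--;
      n_t[old]--;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (n_dt[(size_t)d * K + k] + alpha) *
               (n_tw[(size_t)k * V + w] + beta) / (n_t[k] + Vbeta);
        p[k] = tot;
      }
      double u = unif_rand() * tot;
      int k = 0;
      while (k < K - 1 && p[k] < u) ++k;
      z[t] = k;
      n_dt[(size_t)d * K + k]++;
      n_tw[(size_t)k * V + w]++;
      n_t[k]++;
    }
    if (average && it >= burn_in) {
      for (size_t i = 0; i < acc_dt.size(); ++i) acc_dt[i] += n_dt[i];
      for (size_t i = 0; i < acc_tw.size(); ++i) acc_tw[i] += n_tw[i];
      for (int k = 0; k < K; ++k) acc_t[k] += n_t[k];
      ++n_acc;
    }
  }

  NumericMatrix theta(D, K), phi(K, V);
  if (average && n_acc > 0) {
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k)
        theta(d, k) = (acc_dt[(size_t)d * K + k] / n_acc + alpha) /
                      (n_d[d] + K * alpha);
    for (int k = 0; k < K; ++k)
      for (int w = 0; w < V; ++w)
        phi(k, w) = (acc_tw[(size_t)k * V + w] / n_acc + beta) /
                    (acc_t[k] / n_acc + Vbeta);
  } else {
    for (int d = 0; d < D; ++d)
      for (int k = 0; k < K; ++k)
        theta(d, k) = (n_dt[(size_t)d * K + k] + alpha) /
                      (n_d[d] + K * alpha);
    for (int k = 0; k < K; ++k)
      for (int w = 0; w < V; ++w)
        phi(k, w) = (n_tw[(size_t)k * V + w] + beta) / (n_t[k] + Vbeta);
  }
  return List::create(_["theta"] = theta, _["phi"] = phi);
}
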