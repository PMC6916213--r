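#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for latent Dirichlet allocation.
//
// docs: list of 0-based integer word-id vectors (one per document).
// W: vocabulary size; K: topics; alpha/beta: symmetric Dirichlet priors;
// iters: full sweeps. Uses R's RNG so set.seed() makes runs reproducible.
// Returns the topic-word counts, document-topic counts and the final
// assignment vector per document.
// [[Rcpp::export]]
List lda_gibbs_cpp(List docs, int W, int K, double alpha, double beta,
                   int iters) {
  int D = docs.size();
  std::vector<std::vector<int>> w(D), z(D);
  IntegerMatrix nkw(K, W);       // topic-word counts
  IntegerMatrix ndk(D, K);       // document-topic counts
  IntegerVector nk(K);           // tokens per topic

  for (int d = 0; d < D; ++d) {
    IntegerVector doc = docs[d];
    w[d].assign(doc.begin(), doc.end());
    z[d].resize(doc.size());
    for (size_t i = 0; i < w[d].size(); ++i) {
      int k = (int)(unif_rand() * K);
      if (k == K) k = K - 1;
      z[d][i] = k;
      nkw(k, w[d][i])++;
      ndk(d, k)++;
      nk[k]++;
    }
  }

  std::vector<double> p(K);
  double Wbeta = W * beta;
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < w[d].size(); ++i) {
        int word = w[d][i], k = z[d][i];
        nkw(k, word)--; ndk(d, k)--; nk[k]--;
        double tot = 0.0;
        for (int t = 0; t < K; ++t) {
          p[t] = (nkw(t, word) + beta) / (nk[t] + Wbeta) * (ndk(d, t) + alpha);
          tot += p[t];
        }
        double u = unif_rand() * tot, cum = 0.0;
        int knew = K - 1;
        for (int t = 0; t < K; ++t) {
          cum += p[t];
          if (u <= cum) { knew = t; break; }
        }
        z[d][i] = knew;
        nkw(knew, word)++; ndk(d, knew)++; nk[knew]++;
      }
    }
  }

  List zout(D);
  for (int d = 0; d < D; ++d) zout[d] = IntegerVector(z[d].begin(), z[d].end());
  return List::create(_["nkw"] = nkw, _["ndk"] = ndk, _["z"] = zout);
}
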