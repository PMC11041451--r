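// Skip-gram with negative sampling (word2vec), single-threaded and
// deterministic under a fixed seed. Own 64-bit RNG (splitmix64) so results
// do not depend on R's RNG state. Word ids are 1-based (from R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Splitmix64 {
  uint64_t s;
  explicit Splitmix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static int sample_cdf(const arma::vec& cdf, double u) {
  // first index with cdf >= u (binary search)
  int lo = 0, hi = cdf.n_elem - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf(mid) < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export(name = ".sgns_train_cpp")]]
arma::mat sgns_train_cpp(const List& sentences, int vocab_size, int dim,
                         int window, int negative, int epochs, double lr0,
                         const arma::vec& noise_cdf, int seed) {
  Splitmix64 rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 12345ULL);
  arma::mat W(vocab_size, dim), C(vocab_size, dim, arma::fill::zeros);
  for (int i = 0; i < vocab_size; ++i)
    for (int d = 0; d < dim; ++d)
      W(i, d) = (rng.unif() - 0.5) / dim;

  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_tokens += ((IntegerVector)sentences[s]).size();
  long long budget = std::max(1LL, total_tokens * epochs);
  long long seen = 0;

  arma::rowvec grad_in(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int T = sent.size();
      for (int t = 0; t < T; ++t, ++seen) {
        double lr = lr0 * std::max(0.0001, 1.0 - (double)seen / budget);
        int b = 1 + rng.below(window); // dynamic window
        int center = sent[t] - 1;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int tc = t + off;
          if (tc < 0 || tc >= T) continue;
          int ctx = sent[tc] - 1;
          grad_in.zeros();
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_cdf(noise_cdf, rng.unif());
              if (target == ctx) continue;
              label = 0.0;
            }
            double f = arma::dot(W.row(center), C.row(target));
            double p = 1.0 / (1.0 + std::exp(-f));
            double g = (label - p) * lr;
            grad_in += g * C.row(target);
            C.row(target) += g * W.row(center);
          }
          W.row(center) += grad_in;
        }
      }
    }
  }
  return W;
}
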