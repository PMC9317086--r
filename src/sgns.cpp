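#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Skip-gram with negative sampling over a random-walk corpus.
// Single-threaded with a private xorshift RNG so a given seed reproduces
// the embedding exactly, independent of R's RNG state.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgnsTrain")]]
NumericMatrix sgnsTrain(List walks, int n_nodes, int dim, int window,
                        int epochs, int negative, double alpha, int seed) {
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram^0.75 table for negative sampling
  std::vector<double> counts(n_nodes, 0.0);
  size_t total_tokens = 0;
  int n_walks = walks.size();
  std::vector<std::vector<int>> corpus(n_walks);
  for (int w = 0; w < n_walks; ++w) {
    IntegerVector wk = walks[w];
    corpus[w].assign(wk.begin(), wk.end());
    for (int tok : corpus[w]) {
      counts[tok] += 1.0;
      ++total_tokens;
    }
  }
  if (total_tokens == 0) stop("empty walk corpus");
  const int table_size = 100000;
  std::vector<int> table(table_size);
  double norm = 0.0;
  for (int i = 0; i < n_nodes; ++i) norm += std::pow(counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / norm;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((double)(t + 1) / table_size > cum && i < n_nodes - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / norm;
      }
    }
  }

  const double min_alpha = alpha * 1e-4;
  double processed = 0.0;
  const double budget = (double)total_tokens * epochs;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int w = 0; w < n_walks; ++w) {
      const std::vector<int>& wk = corpus[w];
      int len = (int)wk.size();
      for (int i = 0; i < len; ++i) {
        processed += 1.0;
        double lr = alpha * (1.0 - processed / (budget + 1.0));
        if (lr < min_alpha) lr = min_alpha;
        int b = rng.below(window);  // reduced window, word2vec style
        int lo = i - window + b, hi = i + window - b;
        if (lo < 0) lo = 0;
        if (hi >= len) hi = len - 1;
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int ctx = wk[j];     // vector being updated (syn0 row)
          int center = wk[i];
          double* v = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[rng.below(table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* u = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += v[k] * u[k];
            double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * u[k];
              u[k] += g * v[k];
            }
          }
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
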