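#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Skip-gram with negative sampling, single-threaded and fully deterministic
// given `seed`. Follows the classic word2vec update rules: a linearly decaying
// learning rate, dynamic window shrinking, optional frequent-word subsampling,
// and a unigram^0.75 negative-sampling table.

namespace {

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed ? seed : 1ULL) {}
  // word2vec-style 64-bit LCG
  inline uint64_t next() {
    state = state * 25214903917ULL + 11ULL;
    return state;
  }
  inline double unif() {  // in [0,1)
    return (double)((next() >> 16) & 0xFFFFFFFFULL) / 4294967296.0;
  }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, IntegerVector counts, int dim,
                         int window, int negative, int epochs, double alpha,
                         double min_alpha, double sample, int seed) {
  const int vocab = counts.size();
  if (vocab == 0) stop("empty vocabulary");
  Rng rng((uint64_t)seed * 2654435761ULL + 7ULL);

  // negative-sampling table, unigram counts raised to 3/4
  const int table_size = 1000000;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int i = 0; i < vocab; ++i) z += std::pow((double)counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow((double)counts[0], 0.75) / z;
    for (int t = 0; t < table_size; ++t) {
      table[t] = i;
      if ((double)(t + 1) / table_size > cum && i < vocab - 1) {
        ++i;
        cum += std::pow((double)counts[i], 0.75) / z;
      }
    }
  }

  double total_tokens = 0.0;
  for (int i = 0; i < vocab; ++i) total_tokens += counts[i];

  // syn0: input vectors (returned), syn1: output ("context") vectors
  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const int n_sent = sentences.size();
  // pre-extract sentence pointers
  std::vector<std::vector<int>> sents(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector sv = sentences[s];
    sents[s].assign(sv.begin(), sv.end());
  }

  double trained = 0.0;
  const double train_total = std::max(1.0, total_tokens * epochs);
  std::vector<double> neu1e(dim);
  std::vector<int> kept;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      const std::vector<int>& sen = sents[s];
      kept.clear();
      for (size_t p = 0; p < sen.size(); ++p) {
        int w = sen[p];
        trained += 1.0;
        if (sample > 0) {
          double f = (double)counts[w] / total_tokens;
          double keep = (std::sqrt(f / sample) + 1.0) * (sample / f);
          if (keep < 1.0 && rng.unif() >= keep) continue;
        }
        kept.push_back(w);
      }
      const int len = (int)kept.size();
      double lr = alpha * (1.0 - trained / train_total);
      if (lr < min_alpha) lr = min_alpha;
      for (int pos = 0; pos < len; ++pos) {
        int w = kept[pos];
        int b = (int)(rng.next() % (uint64_t)window);  // dynamic window
        for (int c = pos - (window - b); c <= pos + (window - b); ++c) {
          if (c < 0 || c >= len || c == pos) continue;
          int ctx = kept[c];
          double* l1 = &syn0[(size_t)ctx * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target, label;
            if (d == 0) {
              target = w;
              label = 1;
            } else {
              target = table[(rng.next() >> 16) % table_size];
              if (target == w) continue;
              label = 0;
            }
            double* l2 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += l1[k] * l2[k];
            double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * l2[k];
            for (int k = 0; k < dim; ++k) l2[k] += g * l1[k];
          }
          for (int k = 0; k < dim; ++k) l1[k] += neu1e[k];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
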