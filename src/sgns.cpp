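#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic single-thread skip-gram with negative sampling.
// Own xorshift RNG so results are identical across platforms and
// independent of R's RNG state.
namespace {
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, n)
  uint64_t next_int(uint64_t n) { return next() % n; }
  double next_unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}
}  // namespace

// sentences: list of integer vectors of 0-based vocab ids (-1 = dropped)
// counts: vocab frequencies used for the unigram^0.75 negative table
// [[Rcpp::export(rng = false)]]
NumericMatrix sgns_train_cpp(List sentences, IntegerVector counts, int dim,
                             int window, int negative, int epochs,
                             double alpha, int seed) {
  const int V = counts.size();
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // negative-sampling table (unigram^0.75), 1e6 slots
  const int table_size = 1000000;
  std::vector<int> table(table_size);
  double z = 0.0;
  for (int v = 0; v < V; ++v) z += std::pow((double)counts[v], 0.75);
  double cum = std::pow((double)counts[0], 0.75) / z;
  int v = 0;
  for (int i = 0; i < table_size; ++i) {
    table[i] = v;
    if ((double)(i + 1) / table_size > cum && v < V - 1) {
      ++v;
      cum += std::pow((double)counts[v], 0.75) / z;
    }
  }

  std::vector<double> W((size_t)V * dim), C((size_t)V * dim, 0.0);
  for (size_t i = 0; i < W.size(); ++i)
    W[i] = (rng.next_unif() - 0.5) / dim;

  long long total_tokens = 0;
  const int S = sentences.size();
  std::vector<std::vector<int>> sents(S);
  for (int s = 0; s < S; ++s) {
    IntegerVector iv = sentences[s];
    sents[s].assign(iv.begin(), iv.end());
    total_tokens += iv.size();
  }

  std::vector<double> grad(dim);
  long long processed = 0;
  const long long budget = total_tokens * (long long)epochs;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& sent = sents[s];
      const int n = (int)sent.size();
      for (int t = 0; t < n; ++t) {
        ++processed;
        const int w = sent[t];
        if (w < 0) continue;
        double lr = alpha * (1.0 - (double)processed / (budget + 1.0));
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        const int b = (int)rng.next_int((uint64_t)window) + 1;  // dynamic window
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          const int c = t + off;
          if (c < 0 || c >= n || sent[c] < 0) continue;
          const int ctx = sent[c];
          double* wv = &W[(size_t)w * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = ctx;
              label = 1.0;
            } else {
              target = table[rng.next_int(table_size)];
              if (target == ctx) continue;
              label = 0.0;
            }
            double* cv = &C[(size_t)target * dim];
            double dot = 0.0;
            for (int k = 0; k < dim; ++k) dot += wv[k] * cv[k];
            const double g = (label - sigmoid(dot)) * lr;
            for (int k = 0; k < dim; ++k) {
              grad[k] += g * cv[k];
              cv[k] += g * wv[k];
            }
          }
          for (int k = 0; k < dim; ++k) wv[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int i = 0; i < V; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = W[(size_t)i * dim + k];
  return out;
}
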