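#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Exact max-sum decoding over the label lattice.
// emissions: T x L token scores; trans: L x L transition scores (may contain
// -Inf for forbidden moves); init/fin: length-L start/end scores.
// Returns 1-based label indices of the single highest-scoring valid path.
// Ties break toward the lower label index (deterministic).
// [[Rcpp::export(rng = false)]]
IntegerVector viterbi_decode_cpp(NumericMatrix emissions, NumericMatrix trans,
                                 NumericVector init, NumericVector fin) {
  const int T = emissions.nrow();
  const int L = emissions.ncol();
  IntegerVector path(T);
  if (T == 0) return path;
  const double NEG = -std::numeric_limits<double>::infinity();

  std::vector<double> delta(L), ndelta(L);
  std::vector<std::vector<int>> back(T, std::vector<int>(L, 0));
  for (int l = 0; l < L; ++l) delta[l] = init[l] + emissions(0, l);

  for (int t = 1; t < T; ++t) {
    for (int l = 0; l < L; ++l) {
      double best = NEG;
      int arg = 0;
      for (int p = 0; p < L; ++p) {
        const double v = delta[p] + trans(p, l);
        if (v > best) {
          best = v;
          arg = p;
        }
      }
      ndelta[l] = best + emissions(t, l);
      back[t][l] = arg;
    }
    delta.swap(ndelta);
  }

  double best = NEG;
  int arg = 0;
  for (int l = 0; l < L; ++l) {
    const double v = delta[l] + fin[l];
    if (v > best) {
      best = v;
      arg = l;
    }
  }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = back[t][arg];
    path[t - 1] = arg + 1;
  }
  return path;
}

// Batched decoding: `emissions` stacks consecutive sentences row-wise and
// `lengths` gives each sentence's token count. One call per corpus instead
// of one per sentence.
// [[Rcpp::export(rng = false)]]
IntegerVector viterbi_decode_batch_cpp(NumericMatrix emissions,
                                       IntegerVector lengths,
                                       NumericMatrix trans,
                                       NumericVector init, NumericVector fin) {
  const int L = emissions.ncol();
  const int N = emissions.nrow();
  IntegerVector out(N);
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<double> delta(L), ndelta(L);
  int offset = 0;
  for (int s = 0; s < lengths.size(); ++s) {
    const int T = lengths[s];
    if (T == 0) continue;
    std::vector<int> back((size_t)T * L, 0);
    for (int l = 0; l < L; ++l) delta[l] = init[l] + emissions(offset, l);
    for (int t = 1; t < T; ++t) {
      for (int l = 0; l < L; ++l) {
        double best = NEG;
        int arg = 0;
        for (int p = 0; p < L; ++p) {
          const double v = delta[p] + trans(p, l);
          if (v > best) {
            best = v;
            arg = p;
          }
        }
        ndelta[l] = best + emissions(offset + t, l);
        back[(size_t)t * L + l] = arg;
      }
      delta.swap(ndelta);
    }
    double best = NEG;
    int arg = 0;
    for (int l = 0; l < L; ++l) {
      const double v = delta[l] + fin[l];
      if (v > best) {
        best = v;
        arg = l;
      }
    }
    out[offset + T - 1] = arg + 1;
    for (int t = T - 1; t > 0; --t) {
      arg = back[(size_t)t * L + arg];
      out[offset + t - 1] = arg + 1;
    }
    offset += T;
  }
  return out;
}
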