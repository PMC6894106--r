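// Skip-gram with negative sampling over entity-token documents.
// Single-threaded with a self-contained RNG so that a fixed seed gives
// bit-identical vectors, and so that specialization probability 0 consumes
// exactly the same random stream as plain training.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {
    // scramble a small seed
    for (int i = 0; i < 8; ++i) next();
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 2685821657736338717ULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// One SGNS update for the (input, output) pair plus `negative` samples.
void train_pair(std::vector<double>& syn0, std::vector<double>& syn1,
                int input, int output, int dim, int negative, double lr,
                const std::vector<int>& table, XorShift& rng,
                std::vector<double>& err) {
  std::fill(err.begin(), err.end(), 0.0);
  const size_t l0 = static_cast<size_t>(input) * dim;
  for (int d = 0; d <= negative; ++d) {
    int target;
    double label;
    if (d == 0) {
      target = output;
      label = 1.0;
    } else {
      target = table[rng.below(static_cast<int>(table.size()))];
      if (target == output) continue;
      label = 0.0;
    }
    const size_t l1 = static_cast<size_t>(target) * dim;
    double f = 0.0;
    for (int k = 0; k < dim; ++k) f += syn0[l0 + k] * syn1[l1 + k];
    const double g = (label - sigmoid(f)) * lr;
    for (int k = 0; k < dim; ++k) {
      err[k] += g * syn1[l1 + k];
      syn1[l1 + k] += g * syn0[l0 + k];
    }
  }
  for (int k = 0; k < dim; ++k) syn0[l0 + k] += err[k];
}

}  // namespace

// docs: list of 0-based integer token vectors, one per document.
// counts: token frequencies (unigram distribution for negative sampling).
// groups: per-token integer vectors of alternative thesaurus contexts
//         (0-based vocab ids); empty when the token has no group.
// rate:   probability of training one extra (token, thesaurus-context)
//         pair per center position; 0 disables specialization entirely.
// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(List docs, IntegerVector counts, int dim,
                             int window, int negative, int epochs,
                             double alpha, double rate, List groups,
                             uint32_t seed) {
  const int V = counts.size();
  if (V < 2) stop("vocabulary must contain at least 2 tokens");
  if (dim < 2) stop("embedding dimension must be >= 2");
  XorShift rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);

  // unigram^0.75 negative-sampling table
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    std::vector<double> p(V);
    for (int v = 0; v < V; ++v) {
      p[v] = std::pow(static_cast<double>(counts[v]), 0.75);
      total += p[v];
    }
    int v = 0;
    double cum = p[0] / total;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((i + 1.0) / table_size > cum && v < V - 1) {
        ++v;
        cum += p[v] / total;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<std::vector<int>> sents;
  sents.reserve(docs.size());
  long long n_tokens = 0;
  for (R_xlen_t d = 0; d < docs.size(); ++d) {
    IntegerVector iv = docs[d];
    sents.emplace_back(iv.begin(), iv.end());
    n_tokens += iv.size();
  }
  std::vector<std::vector<int>> grp(V);
  for (int v = 0; v < V; ++v) {
    IntegerVector gv = groups[v];
    grp[v].assign(gv.begin(), gv.end());
  }

  const double total_steps = static_cast<double>(n_tokens) * epochs + 1.0;
  long long processed = 0;
  std::vector<double> err(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& sen : sents) {
      const int n = static_cast<int>(sen.size());
      for (int i = 0; i < n; ++i) {
        double lr = alpha * (1.0 - processed / total_steps);
        if (lr < alpha * 1e-4) lr = alpha * 1e-4;
        ++processed;
        const int center = sen[i];
        const int reach = window - rng.below(window);  // dynamic window 1..window
        for (int j = i - reach; j <= i + reach; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          train_pair(syn0, syn1, center, sen[j], dim, negative, lr,
                     table, rng, err);
        }
        if (rate > 0.0 && !grp[center].empty() && rng.unif() < rate) {
          const int ctx = grp[center][rng.below(static_cast<int>(grp[center].size()))];
          train_pair(syn0, syn1, center, ctx, dim, negative, lr,
                     table, rng, err);
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < dim; ++k)
      out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
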