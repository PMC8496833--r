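// Shallow two-layer word-embedding trainer: continuous-bag-of-words with
// negative sampling, single-threaded with a private LCG so training is a
// pure function of (corpus, hyperparameters, seed).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Lehmer / MINSTD linear congruential generator, independent of R's RNG.
struct Lcg {
  uint64_t state;
  explicit Lcg(uint64_t seed) : state(seed % 2147483647ULL) {
    if (state == 0) state = 42;
  }
  uint32_t next() {
    state = (state * 48271ULL) % 2147483647ULL;
    return static_cast<uint32_t>(state);
  }
  double unif() { return next() / 2147483647.0; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// docs: list of 0-based integer vectors (token indices into the vocabulary);
// counts: per-word corpus frequency (for the negative-sampling table).
// Returns the |V| x dim input-embedding matrix.
// [[Rcpp::export(name = ".cbow_train")]]
NumericMatrix cbow_train(List docs, IntegerVector counts, int dim,
                         int window, int epochs, int negative,
                         double learning_rate, int seed) {
  const int V = counts.size();
  if (V == 0) stop("empty vocabulary");
  Lcg rng(static_cast<uint64_t>(seed));

  // init: input vectors uniform in (-0.5/dim, 0.5/dim), outputs zero
  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram table with 3/4-power smoothing for negative sampling
  const int table_size = 100000;
  std::vector<int> table(table_size);
  double total = 0.0;
  for (int w = 0; w < V; ++w) total += std::pow((double)counts[w], 0.75);
  {
    int w = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int t = 0; t < table_size; ++t) {
      table[t] = w;
      if ((t + 1.0) / table_size > cum && w < V - 1) {
        ++w;
        cum += std::pow((double)counts[w], 0.75) / total;
      }
    }
  }

  // pre-extract documents
  std::vector<std::vector<int>> corpus;
  corpus.reserve(docs.size());
  long long n_tokens = 0;
  for (int d = 0; d < docs.size(); ++d) {
    IntegerVector v = docs[d];
    corpus.emplace_back(v.begin(), v.end());
    n_tokens += v.size();
  }
  if (n_tokens == 0) stop("empty corpus");

  std::vector<double> hidden(dim), grad(dim);
  const double lr0 = learning_rate;
  long long processed = 0;
  const double total_work = (double)n_tokens * epochs;

  for (int ep = 0; ep < epochs; ++ep) {
    for (const auto& doc : corpus) {
      const int n = (int)doc.size();
      for (int pos = 0; pos < n; ++pos) {
        ++processed;
        // linearly decaying learning rate, floored at 1e-4 * lr0
        double lr = lr0 * (1.0 - processed / (total_work + 1.0));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        // dynamic window as in the reference word2vec implementation
        int b = (int)(rng.next() % (uint32_t)window);
        int lo = pos - window + b, hi = pos + window - b;
        if (lo < 0) lo = 0;
        if (hi > n - 1) hi = n - 1;
        int cn = 0;
        std::fill(hidden.begin(), hidden.end(), 0.0);
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          const double* v = &syn0[(size_t)doc[j] * dim];
          for (int k = 0; k < dim; ++k) hidden[k] += v[k];
          ++cn;
        }
        if (cn == 0) continue;
        for (int k = 0; k < dim; ++k) hidden[k] /= cn;
        std::fill(grad.begin(), grad.end(), 0.0);
        const int target = doc[pos];
        for (int s = 0; s <= negative; ++s) {
          int w; double label;
          if (s == 0) { w = target; label = 1.0; }
          else {
            w = table[rng.next() % table_size];
            if (w == target) continue;
            label = 0.0;
          }
          double* out = &syn1[(size_t)w * dim];
          double f = 0.0;
          for (int k = 0; k < dim; ++k) f += hidden[k] * out[k];
          double g = lr * (label - sigmoid(f));
          for (int k = 0; k < dim; ++k) {
            grad[k] += g * out[k];
            out[k] += g * hidden[k];
          }
        }
        for (int j = lo; j <= hi; ++j) {
          if (j == pos) continue;
          double* v = &syn0[(size_t)doc[j] * dim];
          for (int k = 0; k < dim; ++k) v[k] += grad[k];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int w = 0; w < V; ++w)
    for (int k = 0; k < dim; ++k) out(w, k) = syn0[(size_t)w * dim + k];
  return out;
}
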