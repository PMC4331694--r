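// Skip-gram with negative sampling (SGNS), single-threaded and seeded.
//
// Word ids are 0-based; -1 marks a sequence boundary. Dynamic context window
// (radius drawn uniformly in 1..window per center, as in the reference
// word2vec implementation), unigram^(3/4) negative-sampling table, linear
// learning-rate decay. Deterministic for a fixed seed.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {
struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};
inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}
} // namespace

// [[Rcpp::export]]
NumericMatrix sgns_train_cpp(IntegerVector corpus, int V, NumericVector counts,
                             int dim, int window, int negative, int epochs,
                             double alpha, int seed) {
  if (V <= 1) stop("need at least two word types to train embeddings");
  XorShift64 rng((uint64_t)seed * 2862933555777941757ULL + 3037000493ULL);

  // input (syn0) and output (syn1) vectors
  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // negative-sampling table, unigram counts ^ 0.75
  const int table_n = 100000;
  std::vector<int> table(table_n);
  {
    double total = 0.0;
    std::vector<double> pw(V);
    for (int w = 0; w < V; ++w) { pw[w] = std::pow(counts[w], 0.75); total += pw[w]; }
    int w = 0;
    double cum = pw[0] / total;
    for (int i = 0; i < table_n; ++i) {
      table[i] = w;
      if ((i + 1.0) / table_n > cum && w < V - 1) { ++w; cum += pw[w] / total; }
    }
  }

  const R_xlen_t n = corpus.size();
  const double total_steps = (double)epochs * n + 1.0;
  double processed = 0.0;
  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t pos = 0; pos < n; ++pos, processed += 1.0) {
      const int w = corpus[pos];
      if (w < 0) continue;
      const double lr = alpha * std::max(1e-4, 1.0 - processed / total_steps);
      const int b = 1 + (int)rng.below((uint64_t)window);
      for (int off = -b; off <= b; ++off) {
        if (off == 0) continue;
        const R_xlen_t cpos = pos + off;
        if (cpos < 0 || cpos >= n) continue;
        const int c = corpus[cpos];
        if (c < 0) continue; // sequence boundary: window does not cross it
        // check no boundary between pos and cpos
        bool crossed = false;
        const R_xlen_t lo = std::min(pos, cpos), hi = std::max(pos, cpos);
        for (R_xlen_t j = lo; j <= hi && !crossed; ++j) crossed = corpus[j] < 0;
        if (crossed) continue;
        // predict context c from center w
        double* v = &syn0[(size_t)w * dim];
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int d = 0; d <= negative; ++d) {
          int target; double label;
          if (d == 0) { target = c; label = 1.0; }
          else {
            target = table[rng.below(table_n)];
            if (target == c) continue;
            label = 0.0;
          }
          double* u = &syn1[(size_t)target * dim];
          double dot = 0.0;
          for (int j = 0; j < dim; ++j) dot += v[j] * u[j];
          const double g = (label - sigmoid(dot)) * lr;
          for (int j = 0; j < dim; ++j) { grad[j] += g * u[j]; u[j] += g * v[j]; }
        }
        for (int j = 0; j < dim; ++j) v[j] += grad[j];
      }
    }
  }
  NumericMatrix out(V, dim);
  for (int w = 0; w < V; ++w)
    for (int j = 0; j < dim; ++j) out(w, j) = syn0[(size_t)w * dim + j];
  return out;
}
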