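#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

// PV-DBOW document-embedding trainer with negative sampling, used to learn
// whole-graph vectors from Weisfeiler-Lehman subgraph-token documents.  The
// softmax over the full subgraph vocabulary is approximated by `negative`
// sampled terms per positive (word2vec-style estimator).  Single-threaded
// with its own splitmix64/xorshift RNG: bitwise-reproducible for a given
// (corpus order, seed), independent of R's RNG state.

static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) {
    state = seed ? seed : 0x853c49e6748fea9bULL;
    for (int i = 0; i < 4; ++i) splitmix64(state);
  }
  uint64_t next() { return splitmix64(state); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// docs: list of integer vectors of 0-based token ids; vocab_size: number of
// distinct tokens; counts: token frequencies (for the unigram^0.75 negative
// sampling table).  Returns n_docs x dims matrix of document vectors.
// [[Rcpp::export]]
List doc2vec_dbow(List docs, int vocab_size, IntegerVector counts,
                           int dims, int epochs, int negative,
                           double alpha, double min_alpha, int seed,
                           double subsample) {
  int n_docs = docs.size();
  if (n_docs < 1) stop("empty corpus");
  if (dims < 1) stop("dimensions must be positive");

  std::vector<std::vector<int> > corpus(n_docs);
  long long total_tokens = 0;
  for (int d = 0; d < n_docs; ++d) {
    IntegerVector v = docs[d];
    corpus[d].assign(v.begin(), v.end());
    total_tokens += v.size();
  }
  if (total_tokens == 0) stop("corpus contains no tokens");

  Rng rng((uint64_t)seed);

  // document vectors: small random init; token (output) vectors: zero init
  std::vector<double> dvec((size_t)n_docs * dims);
  std::vector<double> wvec((size_t)vocab_size * dims, 0.0);
  for (size_t i = 0; i < dvec.size(); ++i)
    dvec[i] = (rng.unif() - 0.5) / dims;

  // unigram^(3/4) table for negative sampling
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double tot = 0.0;
    for (int t = 0; t < vocab_size; ++t) tot += std::pow((double)counts[t], 0.75);
    double cum = std::pow((double)counts[0], 0.75) / tot;
    int t = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = t;
      if ((double)(i + 1) / table_size > cum && t < vocab_size - 1) {
        ++t;
        cum += std::pow((double)counts[t], 0.75) / tot;
      }
    }
  }

  // frequent-token subsampling: occurrences of a token with corpus
  // frequency f are kept with prob (sqrt(f/s) + 1) * s/f (word2vec rule),
  // discounting ubiquitous tokens so rarer, discriminative subgraphs shape
  // the vectors
  std::vector<double> keep_prob(vocab_size, 1.0);
  if (subsample > 0) {
    for (int t = 0; t < vocab_size; ++t) {
      double f = (double)counts[t] / total_tokens;
      if (f > subsample) {
        double p = (std::sqrt(f / subsample) + 1.0) * subsample / f;
        keep_prob[t] = p < 1.0 ? p : 1.0;
      }
    }
  }

  std::vector<double> grad(dims);
  long long processed = 0;
  const long long budget = (long long)epochs * total_tokens;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < n_docs; ++d) {
      double *dv = &dvec[(size_t)d * dims];
      const std::vector<int> &doc = corpus[d];
      for (size_t pos = 0; pos < doc.size(); ++pos) {
        double lr = alpha * (1.0 - (double)processed / (budget + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        int target = doc[pos];
        if (keep_prob[target] < 1.0 && rng.unif() > keep_prob[target])
          continue;
        std::fill(grad.begin(), grad.end(), 0.0);
        for (int s = 0; s <= negative; ++s) {
          int w;
          double label;
          if (s == 0) { w = target; label = 1.0; }
          else {
            w = table[rng.next() & (table_size - 1)];
            if (w == target) continue;
            label = 0.0;
          }
          double *wv = &wvec[(size_t)w * dims];
          double f = 0.0;
          for (int j = 0; j < dims; ++j) f += dv[j] * wv[j];
          double g;
          if (f > 8.0) g = (label - 1.0) * lr;
          else if (f < -8.0) g = label * lr;
          else g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
          for (int j = 0; j < dims; ++j) grad[j] += g * wv[j];
          for (int j = 0; j < dims; ++j) wv[j] += g * dv[j];
        }
        for (int j = 0; j < dims; ++j) dv[j] += grad[j];
      }
    }
  }

  NumericMatrix out(n_docs, dims);
  for (int d = 0; d < n_docs; ++d)
    for (int j = 0; j < dims; ++j)
      out(d, j) = dvec[(size_t)d * dims + j];
  NumericMatrix wout(vocab_size, dims);
  for (int t = 0; t < vocab_size; ++t)
    for (int j = 0; j < dims; ++j)
      wout(t, j) = wvec[(size_t)t * dims + j];
  return List::create(_["doc_vectors"] = out, _["token_vectors"] = wout);
}

// Infer a vector for a new document against frozen token vectors (no
// updates to the vocabulary side).  Used for the leakage-free embedding
// mode where held-out graphs must not influence the trained space.
// [[Rcpp::export]]
NumericVector doc2vec_infer(NumericMatrix token_vectors, IntegerVector doc,
                            IntegerVector counts, int epochs, int negative,
                            double alpha, double min_alpha, int seed) {
  int dims = token_vectors.ncol();
  int vocab_size = token_vectors.nrow();
  Rng rng((uint64_t)seed);
  std::vector<double> dv(dims);
  for (int j = 0; j < dims; ++j) dv[j] = (rng.unif() - 0.5) / dims;

  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double tot = 0.0;
    for (int t = 0; t < vocab_size; ++t) tot += std::pow((double)counts[t], 0.75);
    double cum = std::pow((double)counts[0], 0.75) / tot;
    int t = 0;
    for (int i = 0; i < table_size; ++i) {
      table[i] = t;
      if ((double)(i + 1) / table_size > cum && t < vocab_size - 1) {
        ++t;
        cum += std::pow((double)counts[t], 0.75) / tot;
      }
    }
  }
  std::vector<double> grad(dims);
  long long processed = 0;
  const long long budget = (long long)epochs * doc.size();
  for (int ep = 0; ep < epochs; ++ep) {
    for (int pos = 0; pos < doc.size(); ++pos) {
      double lr = alpha * (1.0 - (double)processed / (budget + 1));
      if (lr < min_alpha) lr = min_alpha;
      ++processed;
      int target = doc[pos];
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int s = 0; s <= negative; ++s) {
        int w;
        double label;
        if (s == 0) { w = target; label = 1.0; }
        else {
          w = table[rng.next() & (table_size - 1)];
          if (w == target) continue;
          label = 0.0;
        }
        double f = 0.0;
        for (int j = 0; j < dims; ++j) f += dv[j] * token_vectors(w, j);
        double g;
        if (f > 8.0) g = (label - 1.0) * lr;
        else if (f < -8.0) g = label * lr;
        else g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
        for (int j = 0; j < dims; ++j) grad[j] += g * token_vectors(w, j);
      }
      for (int j = 0; j < dims; ++j) dv[j] += grad[j];
    }
  }
  return NumericVector(dv.begin(), dv.end());
}
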