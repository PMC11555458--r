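// Seeded single-threaded skip-gram with negative sampling (SGNS).
// Deterministic by construction: a private xorshift RNG, no threads.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// splitmix64 for seeding, xorshift128+ for the stream
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    auto mix = [](uint64_t z) {
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      return z ^ (z >> 31);
    };
    s0 = mix(z);
    z += 0x9e3779b97f4a7c15ULL;
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// sentences: list of integer vectors with 1-based token ids in 1..V.
// Returns list(input = V x dim, output = V x dim) weight matrices.
// When tail_average is true the returned matrices are the Polyak average
// of the per-epoch weights over the second half of training, which
// substantially reduces SGD noise in the similarity estimates.
// sample: frequent-token subsampling threshold (word2vec's t, 0 = off):
// an occurrence of token w with corpus frequency f is kept with
// probability sqrt(t/f) + t/f, curbing stopword-like domination.
// [[Rcpp::export(name = ".sgns_train")]]
List sgns_train(List sentences, int vocab_size, int dim,
                int window, int epochs, int negative,
                double lr0, double min_count_pow, int seed,
                bool tail_average, double sample) {
  const int V = vocab_size;
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // unigram counts and the negative-sampling cdf (counts^0.75)
  std::vector<double> counts(V, 0.0);
  long long total_words = 0;
  const int n_sent = sentences.size();
  std::vector<std::vector<int>> corpus(n_sent);
  for (int s = 0; s < n_sent; ++s) {
    IntegerVector sv = sentences[s];
    corpus[s].reserve(sv.size());
    for (int j = 0; j < sv.size(); ++j) {
      int w = sv[j] - 1;
      if (w < 0 || w >= V) stop("token id out of range");
      corpus[s].push_back(w);
      counts[w] += 1.0;
      ++total_words;
    }
  }
  if (total_words == 0) stop("empty corpus");
  std::vector<double> cdf(V);
  double acc = 0.0;
  for (int w = 0; w < V; ++w) {
    acc += std::pow(counts[w], min_count_pow);
    cdf[w] = acc;
  }
  if (acc <= 0) stop("degenerate unigram table");
  for (int w = 0; w < V; ++w) cdf[w] /= acc;
  auto sample_neg = [&]() {
    double u = rng.unif();
    int lo = 0, hi = V - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (cdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const double total_steps =
      static_cast<double>(total_words) * epochs;
  double processed = 0.0;
  std::vector<double> grad(dim);
  std::vector<double> avg0, avg1;
  int n_avg = 0;
  const int avg_from = tail_average ? epochs / 2 : epochs;
  if (tail_average) {
    avg0.assign(syn0.size(), 0.0);
    avg1.assign(syn1.size(), 0.0);
  }

  std::vector<double> keep_prob(V, 1.0);
  if (sample > 0) {
    for (int w = 0; w < V; ++w) {
      const double f = counts[w] / static_cast<double>(total_words);
      if (f > sample) {
        double kp = std::sqrt(sample / f) + sample / f;
        keep_prob[w] = kp < 1.0 ? kp : 1.0;
      }
    }
  }

  std::vector<int> filtered;
  std::vector<int> order(n_sent);
  for (int s = 0; s < n_sent; ++s) order[s] = s;
  for (int ep = 0; ep < epochs; ++ep) {
    // deterministic Fisher-Yates shuffle per epoch: corpus chunk order
    // must not leak into the geometry of per-chunk outcome tokens
    for (int s = n_sent - 1; s > 0; --s) {
      int j = static_cast<int>(rng.next() % static_cast<uint64_t>(s + 1));
      std::swap(order[s], order[j]);
    }
    for (int si = 0; si < n_sent; ++si) {
      const std::vector<int>& raw_sen = corpus[order[si]];
      const std::vector<int>* sen_ptr = &raw_sen;
      if (sample > 0) {
        filtered.clear();
        for (int w : raw_sen) {
          if (keep_prob[w] >= 1.0 || rng.unif() < keep_prob[w])
            filtered.push_back(w);
        }
        sen_ptr = &filtered;
      }
      const std::vector<int>& sen = *sen_ptr;
      const int len = static_cast<int>(sen.size());
      for (int pos = 0; pos < len; ++pos) {
        double lr = lr0 * (1.0 - processed / (total_steps + 1.0));
        if (lr < lr0 * 1e-4) lr = lr0 * 1e-4;
        processed += 1.0;
        const int b = rng.below(window);  // dynamic window shrink
        const int w_eff = window - b;
        for (int off = -w_eff; off <= w_eff; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          const int center = sen[pos];
          const int context = sen[cpos];
          double* v_in = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = context;
              label = 1.0;
            } else {
              target = sample_neg();
              if (target == context) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            const double g = (label - sigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
    if (ep >= avg_from) {
      for (size_t i = 0; i < syn0.size(); ++i) {
        avg0[i] += syn0[i];
        avg1[i] += syn1[i];
      }
      ++n_avg;
    }
  }
  if (n_avg > 0) {
    for (size_t i = 0; i < syn0.size(); ++i) {
      syn0[i] = avg0[i] / n_avg;
      syn1[i] = avg1[i] / n_avg;
    }
  }

  NumericMatrix m0(V, dim), m1(V, dim);
  for (int w = 0; w < V; ++w) {
    for (int d = 0; d < dim; ++d) {
      m0(w, d) = syn0[static_cast<size_t>(w) * dim + d];
      m1(w, d) = syn1[static_cast<size_t>(w) * dim + d];
    }
  }
  return List::create(Named("input") = m0, Named("output") = m1);
}
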