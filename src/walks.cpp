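// Seeded second-order (p, q) random walks over an undirected graph,
// node2vec-style. Single-threaded, private RNG: same seed, same walks.
#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {
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
};
}  // namespace

// edges: 2 x m matrix (1-based endpoints) of an undirected graph.
// Returns an integer matrix (n_nodes * walks_per_node) x walk_length of
// 1-based node ids; rows for isolated nodes are all zero.
// [[Rcpp::export(name = ".node2vec_walks")]]
IntegerMatrix node2vec_walks(IntegerMatrix edges, int n_nodes,
                             int walks_per_node, int walk_length,
                             double p, double q, int seed) {
  std::vector<std::vector<int>> adj(n_nodes);
  for (int e = 0; e < edges.ncol(); ++e) {
    int a = edges(0, e) - 1, b = edges(1, e) - 1;
    if (a < 0 || a >= n_nodes || b < 0 || b >= n_nodes)
      stop("edge endpoint out of range");
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  for (auto& nb : adj) std::sort(nb.begin(), nb.end());
  auto connected = [&](int a, int b) {
    const std::vector<int>& nb = adj[a];
    return std::binary_search(nb.begin(), nb.end(), b);
  };

  Rng rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1ULL);
  IntegerMatrix out(n_nodes * walks_per_node, walk_length);
  std::vector<double> wts;
  int row = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int v = 0; v < n_nodes; ++v, ++row) {
      if (adj[v].empty()) continue;  // left as zeros, caller drops
      int prev = -1, cur = v;
      out(row, 0) = cur + 1;
      for (int step = 1; step < walk_length; ++step) {
        const std::vector<int>& nb = adj[cur];
        if (nb.empty()) break;
        int nxt;
        if (prev < 0 || (p == 1.0 && q == 1.0)) {
          nxt = nb[static_cast<int>(rng.next() % nb.size())];
        } else {
          wts.resize(nb.size());
          double tot = 0.0;
          for (size_t j = 0; j < nb.size(); ++j) {
            double w;
            if (nb[j] == prev) w = 1.0 / p;
            else if (connected(nb[j], prev)) w = 1.0;
            else w = 1.0 / q;
            tot += w;
            wts[j] = tot;
          }
          double u = rng.unif() * tot;
          size_t lo = 0, hi = nb.size() - 1;
          while (lo < hi) {
            size_t mid = (lo + hi) / 2;
            if (wts[mid] < u) lo = mid + 1; else hi = mid;
          }
          nxt = nb[lo];
        }
        out(row, step) = nxt + 1;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return out;
}
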