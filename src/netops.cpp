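// Sampling of edge-switching proposals.  Kept in C++ because the optimizer
// calls it once per local-search attempt.  Randomness comes from R's global
// RNG stream.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int draw(int n) { // uniform int in [0, n)
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

static bool adjacent(const std::vector<std::vector<int> >& adj, int a, int b) {
  const std::vector<int>& na = adj[a];
  for (size_t q = 0; q < na.size(); ++q)
    if (na[q] == b) return true;
  return false;
}

// Select u (deg >= 2), neighbors i, j of u (deg >= 2, j-i absent), edge j-k
// and edge i-m with all five nodes distinct and k-m absent.  Returns
// c(found, u, i, j, k, m) with 1-based node ids (0s when not found).
// [[Rcpp::export]]
IntegerVector cpp_node_select(int n, IntegerVector ei, IntegerVector ej,
                              int max_attempts) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < ei.size(); ++e) {
    adj[ei[e]].push_back(ej[e]);
    adj[ej[e]].push_back(ei[e]);
  }
  std::vector<int> hubs;
  for (int v = 0; v < n; ++v)
    if ((int)adj[v].size() >= 2) hubs.push_back(v);
  IntegerVector fail = IntegerVector::create(0, 0, 0, 0, 0, 0);
  if (hubs.empty()) return fail;

  std::vector<int> buf;
  for (int attempt = 0; attempt < max_attempts; ++attempt) {
    const int u = hubs[draw((int)hubs.size())];
    buf.clear();
    for (size_t q = 0; q < adj[u].size(); ++q) {
      const int w = adj[u][q];
      if ((int)adj[w].size() >= 2) buf.push_back(w);
    }
    if (buf.size() < 2) continue;
    const int qi = draw((int)buf.size());
    int qj = draw((int)buf.size() - 1);
    if (qj >= qi) ++qj;
    const int i = buf[qi], j = buf[qj];
    if (adjacent(adj, i, j)) continue; // j-i must be addable
    buf.clear();
    for (size_t q = 0; q < adj[j].size(); ++q) {
      const int w = adj[j][q];
      if (w != u && w != i && w != j) buf.push_back(w);
    }
    if (buf.empty()) continue;
    const int k = buf[draw((int)buf.size())];
    buf.clear();
    for (size_t q = 0; q < adj[i].size(); ++q) {
      const int w = adj[i][q];
      if (w != u && w != i && w != j && w != k && !adjacent(adj, k, w))
        buf.push_back(w);
    }
    if (buf.empty()) continue;
    const int m = buf[draw((int)buf.size())];
    return IntegerVector::create(1, u + 1, i + 1, j + 1, k + 1, m + 1);
  }
  return fail;
}
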