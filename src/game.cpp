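// Core Prisoner's Dilemma engine: payoff accumulation, the three synchronous
// strategy-update rules, and the equilibrium cooperation-level evaluator.
// All randomness is drawn from R's global RNG stream (unif_rand), so results
// are bit-reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Compressed adjacency built from a 0-based edge list.
struct Net {
  int n;
  std::vector<int> ptr; // size n + 1
  std::vector<int> adj; // size 2 * m, neighbors of i at [ptr[i], ptr[i+1])
};

static Net build_net(int n, const IntegerVector& ei, const IntegerVector& ej) {
  Net net;
  net.n = n;
  const int m = ei.size();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    ++deg[ei[e]];
    ++deg[ej[e]];
  }
  net.ptr.assign(n + 1, 0);
  for (int i = 0; i < n; ++i) net.ptr[i + 1] = net.ptr[i] + deg[i];
  net.adj.assign(2 * m, 0);
  std::vector<int> fill(n, 0);
  for (int e = 0; e < m; ++e) {
    const int a = ei[e], b = ej[e];
    net.adj[net.ptr[a] + fill[a]++] = b;
    net.adj[net.ptr[b] + fill[b]++] = a;
  }
  return net;
}

// strategy coding: 1 = cooperate, 0 = defect
static inline double pay_entry(int sx, int sy, double T, double R, double P,
                               double S) {
  if (sx == 1) return sy == 1 ? R : S;
  return sy == 1 ? T : P;
}

static void payoffs(const Net& net, const std::vector<int>& s, double T,
                    double R, double P, double S, std::vector<double>& pay) {
  for (int i = 0; i < net.n; ++i) {
    double acc = 0.0;
    for (int p = net.ptr[i]; p < net.ptr[i + 1]; ++p)
      acc += pay_entry(s[i], s[net.adj[p]], T, R, P, S);
    pay[i] = acc;
  }
}

// Recolonization rule: site x is retained with prob prod_y (1 - W_y) where
// W_y = max(0, P_y - P_x) / (D * max(d_x, d_y)); otherwise a neighbor is
// chosen with relative probability W_y / sum W.
static void step_recolonize(const Net& net, const std::vector<int>& s,
                            const std::vector<double>& pay, double D,
                            std::vector<int>& out, std::vector<double>& wbuf) {
  for (int x = 0; x < net.n; ++x) {
    const int dx = net.ptr[x + 1] - net.ptr[x];
    double retain = 1.0, wsum = 0.0;
    for (int p = net.ptr[x], q = 0; p < net.ptr[x + 1]; ++p, ++q) {
      const int y = net.adj[p];
      const int dy = net.ptr[y + 1] - net.ptr[y];
      double w = 0.0;
      if (pay[y] > pay[x]) {
        const int dmax = dx > dy ? dx : dy;
        w = (pay[y] - pay[x]) / (D * dmax);
      }
      wbuf[q] = w;
      wsum += w;
      retain *= (1.0 - w);
    }
    out[x] = s[x];
    if (wsum > 0.0 && unif_rand() >= retain) {
      double target = unif_rand() * wsum, acc = 0.0;
      int pick = net.ptr[x + 1] - net.ptr[x] - 1; // fallback: last neighbor
      for (int q = 0; q < dx; ++q) {
        acc += wbuf[q];
        if (target < acc) { pick = q; break; }
      }
      out[x] = s[net.adj[net.ptr[x] + pick]];
    }
  }
}

// Fermi rule: each learner z picks one neighbor w uniformly and adopts its
// strategy with probability 1 / (1 + exp((P_z - P_w) / k)).
static void step_fermi(const Net& net, const std::vector<int>& s,
                       const std::vector<double>& pay, double k,
                       std::vector<int>& out) {
  for (int z = 0; z < net.n; ++z) {
    const int dz = net.ptr[z + 1] - net.ptr[z];
    out[z] = s[z];
    if (dz == 0) continue;
    int q = (int)(unif_rand() * dz);
    if (q >= dz) q = dz - 1;
    const int w = net.adj[net.ptr[z] + q];
    const double x = (pay[z] - pay[w]) / k;
    // numerically stable logistic
    const double prob = x >= 0 ? std::exp(-x) / (1.0 + std::exp(-x))
                               : 1.0 / (1.0 + std::exp(x));
    if (unif_rand() < prob) out[z] = s[w];
  }
}

// Unconditional imitation: copy the strictly richer best neighbor; ties among
// equally best neighbors broken uniformly at random.
static void step_unconditional(const Net& net, const std::vector<int>& s,
                               const std::vector<double>& pay,
                               std::vector<int>& out) {
  for (int x = 0; x < net.n; ++x) {
    double best = -HUGE_VAL;
    int nbest = 0;
    for (int p = net.ptr[x]; p < net.ptr[x + 1]; ++p) {
      const double py = pay[net.adj[p]];
      if (py > best) { best = py; nbest = 1; }
      else if (py == best) ++nbest;
    }
    out[x] = s[x];
    if (nbest == 0 || best <= pay[x]) continue;
    int pick = 0;
    if (nbest > 1) {
      pick = (int)(unif_rand() * nbest);
      if (pick >= nbest) pick = nbest - 1;
    }
    int seen = 0;
    for (int p = net.ptr[x]; p < net.ptr[x + 1]; ++p) {
      if (pay[net.adj[p]] == best) {
        if (seen == pick) { out[x] = s[net.adj[p]]; break; }
        ++seen;
      }
    }
  }
}

static void one_step(const Net& net, int rule, const std::vector<int>& s,
                     const std::vector<double>& pay, double D, double k,
                     std::vector<int>& out, std::vector<double>& wbuf) {
  switch (rule) {
    case 0: step_recolonize(net, s, pay, D, out, wbuf); break;
    case 1: step_fermi(net, s, pay, k, out); break;
    case 2: step_unconditional(net, s, pay, out); break;
    default: stop("unknown rule code");
  }
}

static int max_degree(const Net& net) {
  int md = 0;
  for (int i = 0; i < net.n; ++i) {
    const int d = net.ptr[i + 1] - net.ptr[i];
    if (d > md) md = d;
  }
  return md;
}

// [[Rcpp::export]]
NumericVector cpp_accumulate_payoffs(int n, IntegerVector ei, IntegerVector ej,
                                     IntegerVector strat, double T, double R,
                                     double P, double S) {
  Net net = build_net(n, ei, ej);
  std::vector<int> s(strat.begin(), strat.end());
  std::vector<double> pay(n);
  payoffs(net, s, T, R, P, S, pay);
  return NumericVector(pay.begin(), pay.end());
}

// One synchronous generation.  rule: 0 = recolonize, 1 = fermi,
// 2 = unconditional.
// [[Rcpp::export]]
IntegerVector cpp_step(int n, IntegerVector ei, IntegerVector ej,
                       IntegerVector strat, int rule, double T, double R,
                       double P, double S, double k) {
  Net net = build_net(n, ei, ej);
  std::vector<int> s(strat.begin(), strat.end());
  std::vector<double> pay(n);
  payoffs(net, s, T, R, P, S, pay);
  std::vector<int> out(n);
  std::vector<double> wbuf(max_degree(net));
  one_step(net, rule, s, pay, T - S, k, out, wbuf);
  return IntegerVector(out.begin(), out.end());
}

// Full equilibrium evaluation: random (or forced) initial strategies,
// `transient` generations discarded, cooperation frequency averaged over the
// following `averaging` generations.  Homogeneous states are absorbing under
// all three rules, so once reached the remaining window is filled with the
// constant frequency.
// [[Rcpp::export]]
double cpp_evaluate(int n, IntegerVector ei, IntegerVector ej, int rule,
                    double T, double R, double P, double S, double k,
                    int transient, int averaging, IntegerVector init) {
  Net net = build_net(n, ei, ej);
  std::vector<int> s(n), nxt(n);
  if (init.size() == n) {
    for (int i = 0; i < n; ++i) s[i] = init[i];
  } else {
    for (int i = 0; i < n; ++i) s[i] = unif_rand() < 0.5 ? 1 : 0;
  }
  std::vector<double> pay(n);
  std::vector<double> wbuf(max_degree(net));
  const double D = T - S;

  int ncoop = 0;
  for (int i = 0; i < n; ++i) ncoop += s[i];
  double acc = 0.0;
  int done = 0;
  const int total = transient + averaging;
  for (int g = 0; g < total; ++g) {
    if (ncoop == 0 || ncoop == n) break; // absorbing
    payoffs(net, s, T, R, P, S, pay);
    one_step(net, rule, s, pay, D, k, nxt, wbuf);
    s.swap(nxt);
    ncoop = 0;
    for (int i = 0; i < n; ++i) ncoop += s[i];
    if (g >= transient) {
      acc += (double)ncoop / n;
      ++done;
    }
  }
  if (done < averaging) // absorbed: remaining generations are constant
    acc += (double)(averaging - done) * ncoop / n;
  return acc / averaging;
}
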