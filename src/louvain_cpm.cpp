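#include <Rcpp.h>
#include <random>
#include <vector>
#include <numeric>
using namespace Rcpp;

// Louvain-style optimisation of the constant-Potts quality
//   Q_un = sum_{i != j} (w_ij - gamma) * delta(c_i, c_j)
// on a dense symmetric (possibly signed) weight matrix. Node "sizes" track
// how many original vertices a super-node aggregates, so the constant null
// contributes gamma * s_i * s_j per merged pair. Self-weights accumulated
// during aggregation are constant under local moves and can be ignored.

struct Level {
  std::vector<double> W;   // k x k dense, column-major
  std::vector<double> sz;  // super-node sizes
  int k;
  double at(int i, int j) const { return W[(size_t)j * k + i]; }
};

static bool local_move(Level &lev, std::vector<int> &comm, double gamma,
                       std::mt19937 &rng) {
  int k = lev.k;
  std::vector<int> order(k);
  std::iota(order.begin(), order.end(), 0);
  std::shuffle(order.begin(), order.end(), rng);
  std::vector<double> comm_size(k, 0.0);
  for (int v = 0; v < k; ++v) comm_size[comm[v]] += lev.sz[v];
  std::vector<double> wvc(k);
  bool any_move = false, improved = true;
  int guard = 0;
  while (improved && guard++ < 200) {
    improved = false;
    for (int oi = 0; oi < k; ++oi) {
      int v = order[oi];
      int cv = comm[v];
      std::fill(wvc.begin(), wvc.end(), 0.0);
      for (int j = 0; j < k; ++j)
        if (j != v) wvc[comm[j]] += lev.at(v, j);
      // removal cost from own community (v excluded from its size)
      double base = wvc[cv] - gamma * lev.sz[v] * (comm_size[cv] - lev.sz[v]);
      double best_gain = 0.0;
      int best_c = cv;
      for (int c = 0; c < k; ++c) {
        if (c == cv) continue;
        double gain = (wvc[c] - gamma * lev.sz[v] * comm_size[c]) - base;
        if (gain > best_gain + 1e-12) { best_gain = gain; best_c = c; }
      }
      if (best_c != cv) {
        comm_size[cv] -= lev.sz[v];
        comm_size[best_c] += lev.sz[v];
        comm[v] = best_c;
        improved = true;
        any_move = true;
      }
    }
  }
  return any_move;
}

static void relabel(std::vector<int> &comm, int &n_comm) {
  std::vector<int> map(comm.size(), -1);
  n_comm = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = n_comm++;
    comm[i] = map[comm[i]];
  }
}

// [[Rcpp::export(name = ".louvain_cpm_cpp")]]
IntegerVector louvain_cpm_cpp(NumericMatrix w, double gamma, int seed) {
  int n = w.nrow();
  std::mt19937 rng((unsigned)seed);
  Level lev;
  lev.k = n;
  lev.W.assign(w.begin(), w.end());
  for (int i = 0; i < n; ++i) lev.W[(size_t)i * n + i] = 0.0;
  lev.sz.assign(n, 1.0);
  std::vector<int> membership(n);
  std::iota(membership.begin(), membership.end(), 0);

  while (true) {
    std::vector<int> comm(lev.k);
    std::iota(comm.begin(), comm.end(), 0);
    local_move(lev, comm, gamma, rng);
    int n_comm;
    relabel(comm, n_comm);
    for (int i = 0; i < n; ++i) membership[i] = comm[membership[i]];
    if (n_comm == lev.k) break;  // no aggregation possible
    // aggregate
    Level nxt;
    nxt.k = n_comm;
    nxt.W.assign((size_t)n_comm * n_comm, 0.0);
    nxt.sz.assign(n_comm, 0.0);
    for (int v = 0; v < lev.k; ++v) nxt.sz[comm[v]] += lev.sz[v];
    for (int i = 0; i < lev.k; ++i)
      for (int j = 0; j < lev.k; ++j)
        if (i != j)
          nxt.W[(size_t)comm[j] * n_comm + comm[i]] += lev.at(i, j);
    // merged self-weights (comm[i]==comm[j]) are constant; drop them
    for (int c = 0; c < n_comm; ++c) nxt.W[(size_t)c * n_comm + c] = 0.0;
    lev = nxt;
  }
  int n_comm;
  relabel(membership, n_comm);
  return IntegerVector(membership.begin(), membership.end());
}
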