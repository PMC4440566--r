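#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact editing objectives by exhaustive enumeration of the solution
// space: every solution graph is determined by a clustering (cluster
// editing), a clustering scored with per-cluster splittance (split cluster
// editing), or a periphery set plus a clustering of the rest (monopolar
// editing). Clusterings are enumerated as restricted growth strings, so
// each set partition is visited exactly once.

namespace {

// splittance of an induced degree sequence (already extracted)
int splittance_of(std::vector<int> &d) {
  if (d.empty()) return 0;
  std::sort(d.begin(), d.end(), std::greater<int>());
  int n = d.size(), k = 0, sum_top = 0, sum_all = 0;
  for (int i = 0; i < n; ++i) sum_all += d[i];
  int run = 0;
  for (int i = 0; i < n; ++i) {
    run += d[i];
    if (d[i] >= i) { k = i + 1; sum_top = run; }
  }
  return (k * (k - 1) - sum_top + (sum_all - sum_top)) / 2;
}

struct Oracle {
  int n = 0, mode = 0;  // 0 sce, 1 me, 2 ce
  std::vector<std::vector<char>> adj;
  std::vector<int> assign;   // block id; -1 = periphery (me only)
  std::vector<int> bestassign;
  long long best = 0;

  long long eval() const {
    long long cost = 0;
    int nblock = 0;
    for (int v = 0; v < n; ++v) nblock = std::max(nblock, assign[v] + 1);
    // pairwise terms
    for (int u = 0; u < n; ++u) {
      for (int v = u + 1; v < n; ++v) {
        bool e = adj[u][v];
        int au = assign[u], av = assign[v];
        if (au == -1 && av == -1) {
          if (e) ++cost;                      // periphery must be independent
        } else if (au == -1 || av == -1) {
          // periphery-cluster pairs are free (me); unreachable otherwise
        } else if (au == av) {
          if (mode != 0 && !e) ++cost;        // complete clusters (me, ce)
        } else {
          if (e) ++cost;                      // edges between clusters
        }
      }
    }
    if (mode == 0) {
      // per-cluster split editing via splittance
      for (int b = 0; b < nblock; ++b) {
        std::vector<int> mem;
        for (int v = 0; v < n; ++v) if (assign[v] == b) mem.push_back(v);
        if (mem.size() < 2) continue;
        std::vector<int> deg(mem.size(), 0);
        for (size_t i = 0; i < mem.size(); ++i)
          for (size_t j = i + 1; j < mem.size(); ++j)
            if (adj[mem[i]][mem[j]]) { ++deg[i]; ++deg[j]; }
        cost += splittance_of(deg);
      }
    }
    return cost;
  }

  void rec(int i, int maxb) {
    if (i == n) {
      long long c = eval();
      if (c < best) { best = c; bestassign = assign; }
      return;
    }
    if (mode == 1) {
      assign[i] = -1;
      rec(i + 1, maxb);
    }
    for (int b = 0; b <= maxb; ++b) {
      assign[i] = b;
      rec(i + 1, std::max(maxb, b + 1));
    }
    assign[i] = 0;
  }
};

}  // namespace

// [[Rcpp::export]]
List partition_oracle_cpp(LogicalMatrix adjacency, int mode) {
  Oracle O;
  O.n = adjacency.nrow();
  O.mode = mode;
  O.adj.assign(O.n, std::vector<char>(O.n, 0));
  for (int i = 0; i < O.n; ++i)
    for (int j = 0; j < O.n; ++j) O.adj[i][j] = adjacency(i, j) ? 1 : 0;
  O.assign.assign(O.n, 0);
  O.bestassign = O.assign;
  O.best = (long long)O.n * O.n;  // delete-everything upper bound, loose
  if (O.n == 0) {
    return List::create(_["objective"] = 0.0,
                        _["assignment"] = IntegerVector(0));
  }
  O.best = O.eval() + 1;  // ensure at least one assignment is recorded
  O.rec(0, 0);
  return List::create(
      _["objective"] = (double)O.best,
      _["assignment"] = IntegerVector(O.bestassign.begin(), O.bestassign.end()));
}
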