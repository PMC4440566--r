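#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <random>
using namespace Rcpp;

// Simulated annealing on vertex clusterings. For a fixed clustering the
// editing cost is evaluated exactly: edges between clusters are cut and
// each cluster is repaired optimally -- via splittance for the split
// cluster model, via completion for the cluster model; in the monopolar
// model a shared periphery (block -1) additionally has its internal edges
// deleted while periphery-cluster edges are free. Moves relocate one
// vertex to a neighbor's cluster, a fresh empty cluster, or (monopolar)
// the shared periphery; a worsening move of size delta is accepted with
// probability exp(-delta/T) while T is cooled from T0 towards zero.

namespace {

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

struct Annealer {
  int n = 0, mode = 0;  // 0 sce, 1 me, 2 ce
  std::vector<std::vector<char>> adj;
  std::vector<std::vector<int>> nbr;

  std::vector<int> cluster;                // -1 = periphery (me)
  std::vector<std::vector<int>> members;   // per cluster id
  std::vector<int> free_ids;
  std::vector<int> din;                    // neighbors in own cluster (sce)
  std::vector<long long> sp;               // per-cluster splittance (sce)
  long long cost = 0;

  std::mt19937 gen;
  double u01() { return gen() * (1.0 / 4294967296.0); }
  int rint(int k) { return (int)(gen() % (unsigned)k); }

  long long full_cost(const std::vector<int> &cl) const {
    long long c = 0;
    for (int u = 0; u < n; ++u)
      for (int v = u + 1; v < n; ++v) {
        bool e = adj[u][v];
        int au = cl[u], av = cl[v];
        if (au == -1 && av == -1) { if (e) ++c; }
        else if (au == -1 || av == -1) { }
        else if (au == av) { if (mode != 0 && !e) ++c; }
        else if (e) ++c;
      }
    if (mode == 0) {
      int nb = 0;
      for (int v = 0; v < n; ++v) nb = std::max(nb, cl[v] + 1);
      for (int b = 0; b < nb; ++b) {
        std::vector<int> mem;
        for (int v = 0; v < n; ++v) if (cl[v] == b) mem.push_back(v);
        std::vector<int> deg(mem.size(), 0);
        for (size_t i = 0; i < mem.size(); ++i)
          for (size_t j = i + 1; j < mem.size(); ++j)
            if (adj[mem[i]][mem[j]]) { ++deg[i]; ++deg[j]; }
        c += splittance_of(deg);
      }
    }
    return c;
  }

  void reset() {
    cluster.assign(n, 0);
    members.assign(n, {});
    free_ids.clear();
    for (int v = 0; v < n; ++v) { cluster[v] = v; members[v] = {v}; }
    din.assign(n, 0);
    sp.assign(n, 0);
    long long m = 0;
    for (int u = 0; u < n; ++u)
      for (int v = u + 1; v < n; ++v) if (adj[u][v]) ++m;
    cost = m;  // all singletons: every edge is between clusters
  }

  long long cluster_splittance(int id, int skip, int extra) const {
    // splittance of members[id], optionally without vertex `skip` or with
    // vertex `extra` added; degrees taken inside the modified member set
    std::vector<int> deg;
    deg.reserve(members[id].size() + 1);
    for (int u : members[id]) {
      if (u == skip) continue;
      int d = din[u];
      if (skip >= 0 && adj[u][skip]) --d;
      if (extra >= 0 && adj[u][extra]) ++d;
      deg.push_back(d);
    }
    if (extra >= 0) {
      int d = 0;
      for (int u : members[id]) if (u != skip && adj[u][extra]) ++d;
      deg.push_back(d);
    }
    return splittance_of(deg);
  }

  // delta for moving v to cluster `to` (-1 = periphery, -2 = fresh)
  long long move_delta(int v, int to, int &fresh_id) {
    fresh_id = -1;
    int from = cluster[v];
    int target = to;
    if (to == -2) {
      fresh_id = free_ids.back();
      target = fresh_id;
    }
    if (mode == 0) {
      int nA = din[v];
      int nB = 0;
      if (target >= 0)
        for (int u : members[target]) if (adj[u][v]) ++nB;
      long long d = nA - nB;
      d += cluster_splittance(from, v, -1) - sp[from];
      if (target >= 0)
        d += cluster_splittance(target, -1, v) - sp[target];
      return d;
    }
    // monopolar / cluster model: pairwise-local recomputation
    long long before = 0, after = 0;
    for (int u = 0; u < n; ++u) {
      if (u == v) continue;
      bool e = adj[u][v];
      int au = cluster[u];
      // contribution of pair (u, v) under assignment x for v
      auto contrib = [&](int x) -> int {
        if (au == -1 && x == -1) return e ? 1 : 0;
        if (au == -1 || x == -1) return 0;
        if (au == x) return e ? 0 : 1;
        return e ? 1 : 0;
      };
      before += contrib(from);
      after += contrib(to == -2 ? target : to);
    }
    return after - before;
  }

  void apply_move(int v, int to, int fresh_id) {
    int from = cluster[v];
    int target = (to == -2) ? fresh_id : to;
    if (to == -2) free_ids.pop_back();
    // leave `from`
    if (from >= 0) {
      std::vector<int> &mf = members[from];
      mf.erase(std::find(mf.begin(), mf.end(), v));
      if (mf.empty()) free_ids.push_back(from);
    }
    if (mode == 0) {
      for (int u : nbr[v]) {
        if (cluster[u] == from && from >= 0) --din[u];
        if (cluster[u] == target && target >= 0) ++din[u];
      }
    }
    cluster[v] = target;
    if (target >= 0) {
      members[target].push_back(v);
      if (mode == 0) {
        int d = 0;
        for (int u : members[target]) if (u != v && adj[u][v]) ++d;
        din[v] = d;
      }
    } else {
      din[v] = 0;
    }
    if (mode == 0) {
      if (from >= 0) sp[from] = cluster_splittance(from, -1, -1);
      if (target >= 0) sp[target] = cluster_splittance(target, -1, -1);
    }
  }

  // admissible targets for v: distinct neighbor clusters, a fresh cluster
  // when that is not a no-op, and (me) the shared periphery
  std::vector<int> targets_of(int v) {
    std::vector<int> t;
    int own = cluster[v];
    for (int u : nbr[v]) {
      int cu = cluster[u];
      if (cu >= 0 && cu != own &&
          std::find(t.begin(), t.end(), cu) == t.end())
        t.push_back(cu);
    }
    bool singleton = (own >= 0 && members[own].size() == 1);
    if (!singleton && !free_ids.empty()) t.push_back(-2);
    if (mode == 1 && own != -1) t.push_back(-1);
    return t;
  }
};

}  // namespace

// [[Rcpp::export]]
List anneal_cpp(LogicalMatrix adjacency, int mode, int steps, int restarts,
                double t0, int schedule, double alpha, double seed,
                bool check) {
  Annealer A;
  A.n = adjacency.nrow();
  A.mode = mode;
  A.adj.assign(A.n, std::vector<char>(A.n, 0));
  A.nbr.assign(A.n, {});
  for (int i = 0; i < A.n; ++i)
    for (int j = 0; j < A.n; ++j)
      if (adjacency(i, j) && i != j) A.adj[i][j] = 1;
  for (int i = 0; i < A.n; ++i)
    for (int j = 0; j < A.n; ++j)
      if (A.adj[i][j]) A.nbr[i].push_back(j);
  A.gen.seed((unsigned long long)seed);

  if (A.n == 0) {
    return List::create(_["cluster"] = IntegerVector(0), _["cost"] = 0.0,
                        _["restart_best"] = NumericVector(0));
  }

  std::vector<int> bestcl;
  long long bestcost = -1;
  NumericVector restart_best(restarts);

  for (int r = 0; r < restarts; ++r) {
    A.reset();
    long long rbest = A.cost;
    std::vector<int> rbestcl = A.cluster;
    for (int t = 0; t < steps; ++t) {
      double T = (schedule == 0)
                     ? t0 * (1.0 - (double)t / steps)
                     : t0 * std::pow(alpha, t);
      int v = -1;
      std::vector<int> tg;
      for (int tries = 0; tries < 20; ++tries) {
        v = A.rint(A.n);
        tg = A.targets_of(v);
        if (!tg.empty()) break;
      }
      if (tg.empty()) continue;
      int to = tg[A.rint((int)tg.size())];
      int fresh_id = -1;
      long long delta = A.move_delta(v, to, fresh_id);
      bool accept = delta <= 0;
      if (!accept && T > 0)
        accept = A.u01() < std::exp(-(double)delta / T);
      if (accept) {
        A.apply_move(v, to, fresh_id);
        A.cost += delta;
        if (check) {
          long long fc = A.full_cost(A.cluster);
          if (fc != A.cost)
            stop("incremental cost %lld disagrees with recomputation %lld",
                 A.cost, fc);
        }
        if (A.cost < rbest) { rbest = A.cost; rbestcl = A.cluster; }
      }
    }
    restart_best[r] = (double)rbest;
    if (bestcost < 0 || rbest < bestcost) {
      bestcost = rbest;
      bestcl = rbestcl;
    }
  }
  return List::create(_["cluster"] = IntegerVector(bestcl.begin(), bestcl.end()),
                      _["cost"] = (double)bestcost,
                      _["restart_best"] = restart_best);
}
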