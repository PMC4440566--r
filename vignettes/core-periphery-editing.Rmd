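---
title: "Core-periphery decomposition of interaction networks by graph editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-periphery decomposition of interaction networks by graph editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpedit)
```

## The models

Protein complexes are commonly described by a core-attachment picture: a
stable, densely interacting core plus peripheral proteins with transient
interactions to the core. `cpedit` fits a protein-protein interaction
network *globally* to this picture by edge modification. Under perfect
measurements and the idealized model, the network would fall apart into
core-periphery structures; measurement noise is assumed to flip individual
edges independently, so the most plausible idealized network is one
reachable with a minimum number of edge insertions and deletions. Three
idealizations, of decreasing strictness, are supported:

* **Cluster model** (cluster graph): every connected component is a
  clique; no core/periphery distinction. Forbidden induced subgraph:
  the path P3.
* **Split cluster model**: every connected component is a split graph,
  i.e. partitions into a clique (the core) and an independent set (the
  periphery attached only to that core). Forbidden induced subgraphs:
  C4, C5, P5, necktie (a triangle with a two-edge tail), and bowtie
  (two triangles sharing a vertex).
* **Monopolar model**: one *shared* independent periphery; the remaining
  vertices induce a cluster graph of disjoint cores, and a periphery
  vertex may attach to several cores. The class has infinitely many
  minimal forbidden subgraphs; the unique one on at most five vertices is
  the wheel W4, and exactly 11 more exist on six vertices (the package
  recomputes both facts by enumeration).

The corresponding optimization problems -- SPLIT CLUSTER EDITING (SCE),
MONOPOLAR EDITING (ME), CLUSTER EDITING (CE) -- ask for a minimum set of
edge edits into the class. The optima always satisfy
`k(ME) <= k(SCE) <= k(CE)`, since every cluster graph is a split cluster
graph and every split cluster graph is monopolar (take the union of the
per-component peripheries; they are pairwise non-adjacent across
components). SCE and CE are NP-hard, and even recognizing monopolar graphs
is NP-hard, which motivates the mix of exact search, data reduction and
simulated annealing below.

## Recognition with certificates

A split graph is recognized from its degree sequence alone: with degrees
sorted descending and `k` the largest index with `d[k] >= k - 1`, the
*splittance*

```
s = ( k(k-1) - sum(d[1:k]) + sum(d[(k+1):n]) ) / 2
```

is the minimum number of edits to a split graph, and `s == 0` is
membership. The top-`k` vertices then form a clique and the rest an
independent set, which is the witness partition the package returns (ties
between equal degrees are broken lexicographically, a choice that matters
nowhere but makes every output deterministic).

```{r}
splittance(rep(2, 5))   # the 5-cycle needs two edits
is_split(cp_graph(edges = cbind(c("a", "b"), c("b", "c"))))$partition
```

When a component is not split, a certificate is extracted: an induced 2K2,
C4 or C5 located by a deterministic scan over edge pairs (quadratic rather
than linear time; at the problem sizes this package targets the asymptotic
difference is immaterial, and correctness of the certificate, which is
verified before return, is the contract). For the split *cluster* check a
2K2 inside a connected component is first relocated: following the
shortest path between its two edges one always finds, within five
vertices, an induced 2K2 plus a vertex adjacent to at least one endpoint
of each edge. Zero, one, or two extra edges from that vertex then classify
the five vertices as an induced P5, necktie, or bowtie. The package
verifies each certificate against its positional edge pattern before
returning it, so a recognizer bug cannot silently produce a wrong witness.

Monopolar recognition has no known efficient algorithm; the package
provides `is_monopolar_bruteforce()`, an exhaustive two-coloring with
early pruning guarded to 20 vertices, which doubles as the ground-truth
oracle in the test suite.

## Exact solvers

All exact solvers minimize the number of edge variables `e_uv` differing
from the input over systems of covering rows, generated lazily:

* **Forbidden-subgraph formulation (SCE).** A row per forbidden induced
  subgraph found in the current candidate: at least one of the at most ten
  pairs inside it must change. After each solve, the recognizer harvests
  up to `n` rows by repeatedly deleting one certificate vertex and
  searching again. Two strengthenings are applied when `cuts = TRUE`: a C5
  needs at least two edits (right-hand side 2), and for a P5 `u-v-w-x-y`
  the inequality with coefficient 1/2 on the insertions `uw`, `wy`, `xu`,
  `yv` (each of which creates another forbidden subgraph) and the
  insertion `uy` omitted (it creates a C5). Analogous strengthenings for
  neckties and bowties exist in principle but are not stated precisely
  anywhere, and are deliberately not implemented.
* **Partition formulation (SCE, ME).** Additional binary core indicators
  `c_u`. Independent-set rows `c_u + c_v + (1 - e_uv) >= 1` are added for
  *all* pairs up front (the alternative of adding them only for input
  edges is equivalent at the optimum but the complete set is logically
  safe and cheap at these sizes). P3 rows -- with core indicators on the
  endpoints for SCE, on all three vertices for ME -- are added up front
  for the input graph's induced P3s and lazily for candidate solutions.
  The degree-one rule fixes variables first: a vertex `u` whose only
  neighbor `v` has degree greater than one can always be a periphery
  vertex with no inserted edges (`c_u = 0`, `e_uw = 0` for `w != v`).
  The rule is proved for SCE and is therefore not applied to ME.
* **CE.** P3 rows only.

The integral subproblems are solved by an exact depth-first branch and
bound written in C++: pick a violated row, branch over its unsatisfied
literals on undecided variables, never revisit a variable on a path, prune
with the incumbent and a greedy lower bound from variable-disjoint
violated rows whose literals all cost one. With unit costs and
forbidden-subgraph rows this is precisely the classical `O(10^k)` search
tree; the core indicators add zero-cost branching dimensions. No external
mixed-integer programming backend is used anywhere; the branch and bound
is part of the package and is validated against two independent oracles
(below). Because the engine only ever visits integral assignments, there
is no LP relaxation to cut: the cutting-plane *separation* routine
(`separate_cuts()`, families P3 / C4 / P5 / W4, keeping at most the 500
most violated cuts with violation at least 0.3, candidates enumerated from
the support graph of positive edge values) is exposed and tested as a
component for LP-based backends, while the strengthened C5/P5 rows double
as ordinary valid rows during row generation.

Warm starts follow the reference protocol: the annealing heuristic is run
for 10 restarts and its solution seeds the search as incumbent and upper
bound. If the heuristic solution conflicts with fixed variables it is used
as an upper bound only (plus 0.5 -- costs are integral -- so that an
optimum equal to the bound is still found).

Ties among optimal solutions are broken arbitrarily; only the objective is
contractual. In particular the split partition of a split graph is not
unique, and the core indicators are free to return any valid annotation;
comparisons of recovered cores in the tests therefore go through a
canonical per-component annotation (the top-`k` degree clique).

## Simulated annealing

For a fixed clustering the SCE cost is exact and cheap: edges between
clusters plus the splittance of each cluster's induced degree sequence.
For ME, with a designated shared periphery: edges inside the periphery,
plus edges between clusters, plus missing pairs inside clusters. Each
restart starts from all-singleton clusters (and an empty periphery for ME
-- the reference description specifies the singleton start for SCE only,
and symmetry argues for the same neutral start in ME); a step picks a
uniform vertex and a uniform admissible move: into the cluster of a
neighbor, into a fresh empty cluster (skipped when it would be a no-op),
or, for ME, into the shared periphery. A move worsening the cost by
`delta` is accepted with probability `exp(-delta / T)`.

Defaults mirror the reference setup: 20000 steps per restart, `T0 = 1`,
100 restarts. The cooling schedule is only specified as decreasing to
zero; linear decay `T(t) = T0 (1 - t/steps)` is the default and a
geometric schedule is available behind `anneal_config(schedule =
"geometric")`. Move deltas are computed incrementally (cluster-local
splittance recomputation for SCE, pairwise-local recomputation for ME/CE)
and `anneal_config(check = TRUE)` re-derives the cost from scratch after
every accepted move, which the test suite exercises. A fixed seed yields a
bit-identical trajectory; the C++ generator is seeded directly and
restarts share one stream.

## Synthetic instances

`er_graph(n, p, seed)` draws each pair independently with probability `p`
-- the stress test used for solver comparisons. `planted_instance()`
builds noiseless model instances: disjoint cliques as cores; periphery
vertices independent, attached to their own core (disjoint model) or to
one or more cores (shared model). Attachment uses probability 0.5 per
core vertex by default, redrawn until nonempty, a middle-of-the-road
density at which periphery vertices typically attach to about half a
core. `perturb()` toggles a fixed number of distinct uniformly chosen
pairs, so reversing the noise is always a feasible solution and the
optimum is bounded by the noise size.

What the generator does *not* emulate: degree heterogeneity, overlapping
complexes, correlated measurement error, or the size distribution of real
interactome subnetworks. Passing recovery tests on planted instances
therefore demonstrates correctness of the machinery, not biological
fidelity. Note also that noise genuinely destroys information: deleting
one edge of a planted clique makes demoting the affected vertex to the
periphery free, so no solver -- exact or not -- can be expected to restore
the planted cores from noisy data in every trial; recovery is asserted
exactly at zero noise and within the edit budget under noise.

## Evaluation against known complexes

Gold-standard complexes are filtered per subnetwork: drop complexes with
less than 50% of their members present, restrict the rest to present
members, drop what is left with fewer than three members. A complex is
*detected* by a cluster when at least 50% of the cluster's core lies in
the complex and at least 50% of the complex lies in the cluster; each
complex counts once, attributed to the best-scoring detecting cluster
(largest complex coverage, then largest core purity). A cluster is
*nontrivial* with at least three vertices and at least two core vertices.
Reported per detected complex: core purity, complex coverage, and the
fraction of periphery vertices outside the complex (defined as 0 for an
empty periphery, avoiding 0/0).

For shared-periphery solutions (ME, CE) each cluster's effective periphery
is the neighborhood `N(core)`. The reference graph is configurable: the
monopolar solver uses its own edited graph, where `N(core)` is exactly the
attached periphery; for cluster editing the *input* graph is used instead,
since in the edited cluster graph every component is isolated and the
neighborhood would be empty. GO semantic-similarity coherence scores
depend on an external web service and are out of scope; those columns are
simply absent.

## Problem sizes and numerical choices

The test suite runs the exact solvers exhaustively over all 208
isomorphism classes of graphs on up to six vertices and over 200 seeded
random graphs on up to nine vertices, checks the recognizer against
pattern search over all 1252 classes up to seven vertices, and runs the
annealing quality suite at 2000 steps and 10 restarts over 100 seeded
instances on up to ten vertices -- sizes at which the exhaustive
partition-enumeration oracle (Bell numbers up to `B(10)`) stays exact and
fast. Branch-and-bound uses a node budget (default 5e7) after which the
incumbent is returned flagged non-optimal; all comparisons in the
acceptance suite verify the `optimal` flag implicitly by matching the
oracle. Floating point enters only through the 1/2-coefficient rows and
cut violations; comparisons use a 1e-9 slack. Isomorphism throughout is
delegated to igraph's canonical labeling.

## Limitations

* The exact engine targets desk-scale instances (tens of vertices); it is
  a correctness reference, not a competitor to a commercial MIP solver on
  2000-vertex interactomes. The annealing heuristics are the intended tool
  at scale.
* Certificate extraction is quadratic, not linear, in the worst case.
* Monopolar recognition is exhaustive and guarded; there is no 2-SAT
  special-case recognizer for restricted graph classes.
* Weighted or directed interactions, overlapping cores, and minimum core
  sizes are outside the models.
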