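# Small named graphs and independent oracle helpers used across tests.

path_graph <- function(n, labels = letters[seq_len(n)]) {
  if (n == 1L) return(cp_graph(labels))
  cp_graph(labels, cbind(labels[-n], labels[-1L]))
}

cycle_graph <- function(n, labels = letters[seq_len(n)]) {
  cp_graph(labels, cbind(labels, labels[c(seq_len(n)[-1L], 1L)]))
}

complete_graph <- function(n, labels = letters[seq_len(n)]) {
  cp_graph(labels, t(utils::combn(labels, 2L)))
}

# triangle a-b-v plus path v-c-d
necktie_graph <- function() {
  cp_graph(edges = cbind(c("a", "a", "b", "v", "c"),
                         c("b", "v", "v", "c", "d")))
}

# triangles a-b-v and c-d-v sharing v
bowtie_graph <- function() {
  cp_graph(edges = cbind(c("a", "a", "b", "v", "v", "c"),
                         c("b", "v", "v", "c", "d", "d")))
}

# 4-cycle a-b-c-d plus hub h
w4_graph <- function() {
  cp_graph(edges = rbind(cbind(letters[1:4], letters[c(2:4, 1)]),
                         cbind(letters[1:4], "h")))
}

two_k2_graph <- function() {
  cp_graph(edges = cbind(c("a", "c"), c("b", "d")))
}

# independent split test: exhaustive clique / independent-set 2-coloring
split_by_twocoloring <- function(g) {
  n <- n_vertices(g)
  if (n == 0L) return(TRUE)
  a <- adjacency_matrix(g)
  vs <- g$vertices
  for (mask in 0:(2^n - 1L)) {
    core <- vs[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    peri <- setdiff(vs, core)
    core_ok <- length(core) < 2L ||
      all(a[t(utils::combn(core, 2L))])
    peri_ok <- length(peri) < 2L ||
      !any(a[t(utils::combn(peri, 2L))])
    if (core_ok && peri_ok) return(TRUE)
  }
  FALSE
}

# independent minimum split-editing cost: toggle pair subsets, smallest first
split_edit_bruteforce <- function(g) {
  prs <- cpedit:::all_pairs(g$vertices)
  np <- nrow(prs)
  for (k in 0:np) {
    combos <- if (k == 0L) list(integer()) else asplit(utils::combn(np, k), 2L)
    for (idx in combos) {
      h <- cpedit:::toggle_pairs(g, prs[idx, , drop = FALSE])
      if (split_by_twocoloring(h)) return(k)
    }
  }
  stop("unreachable")
}

# canonical igraph keys of the split cluster obstructions, for the
# pattern-search route that double-checks the recognizer
forbidden_pattern_keys <- function() {
  pats <- list(C4 = cycle_graph(4L), C5 = cycle_graph(5L),
               P5 = path_graph(5L), necktie = necktie_graph(),
               bowtie = bowtie_graph())
  vapply(pats, cpedit:::canonical_key, character(1L))
}

# does g contain an induced subgraph isomorphic to any obstruction?
has_forbidden_by_pattern_search <- function(g, keys = forbidden_pattern_keys()) {
  vs <- g$vertices
  n <- length(vs)
  for (k in 4:5) {
    if (n < k) next
    subs <- utils::combn(vs, k)
    for (j in seq_len(ncol(subs))) {
      sub <- induced_subgraph(g, subs[, j])
      if (k == 4L) {
        deg <- cpedit:::vertex_degrees(sub)
        if (n_edges(sub) == 4L && all(deg == 2L)) return(TRUE)  # C4
      } else {
        if (cpedit:::canonical_key(sub) %in% keys) return(TRUE)
      }
    }
  }
  FALSE
}

# seeded ER benchmark suite shared by solver-agreement tests
er_suite <- function(count, sizes = 5:9, ps = c(0.1, 0.3, 0.5), seed0 = 5000L) {
  lapply(seq_len(count), function(i) {
    er_graph(sizes[1L + (i %% length(sizes))],
             ps[1L + (i %% length(ps))], seed = seed0 + i)
  })
}

# fast solver configuration for small test instances
fast_cfg <- function(seed = 1L) {
  solve_cfg(seed = seed, warm_steps = 2000L, warm_restarts = 4L)
}

canonical_core_sets <- function(g) {
  lapply(cpedit:::split_cluster_partition(g), `[[`, "core")
}
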