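# Ground-truth machinery: brute-force editing by exhaustive edit-set
# enumeration, exact objectives by exhaustive enumeration of clusterings,
# the bounded search tree for split cluster editing, and enumeration of
# minimal forbidden induced subgraphs up to isomorphism.

#' Recognize cluster graphs (every component a clique)
#'
#' @param g A `cp_graph`.
#' @return List with `member` (logical) and `certificate` (a P3
#'   [certificate()], or `NULL`).
#' @export
is_cluster_graph <- function(g) {
  p3 <- induced_p3s(g, cap = 1L)
  if (length(p3) == 0L) {
    list(member = TRUE, certificate = NULL)
  } else {
    list(member = FALSE, certificate = certificate("P3", p3[[1L]]))
  }
}

#' Membership predicate for a target graph class
#'
#' @param cls `"split_cluster"`, `"monopolar"`, or `"cluster"`. All three
#'   classes are hereditary (closed under induced subgraphs).
#' @return A function `cp_graph -> logical`.
#' @export
graph_class_predicate <- function(cls = c("split_cluster", "monopolar", "cluster")) {
  cls <- match.arg(cls)
  switch(cls,
         split_cluster = function(g) is_split_cluster(g)$member,
         monopolar = function(g) is_monopolar_bruteforce(g)$monopolar,
         cluster = function(g) is_cluster_graph(g)$member)
}

#' Minimum edit distance to a graph class by exhaustive enumeration
#'
#' Iterative deepening over k = 0, 1, 2, ...: all edit sets of size k
#' (subsets of vertex pairs, each toggled) are enumerated until one reaches
#' the class. Exact by construction; intended for small graphs.
#'
#' @param g A `cp_graph`.
#' @param cls Class name as in [graph_class_predicate()].
#' @param k_max Optional cap on k; if exceeded, an error is thrown.
#' @param guard Maximum number of vertices accepted.
#' @return List with `objective`, `edits` (a `cp_edit_set`), and `graph`
#'   (the edited graph).
#' @export
brute_force_edit <- function(g, cls = c("split_cluster", "monopolar", "cluster"),
                             k_max = NULL, guard = 9L) {
  cls <- match.arg(cls)
  if (n_vertices(g) > guard) {
    stop("brute_force_edit guard: graph has more than ", guard, " vertices")
  }
  pred <- graph_class_predicate(cls)
  prs <- all_pairs(g$vertices)
  np <- nrow(prs)
  if (is.null(k_max)) k_max <- np
  for (k in 0:k_max) {
    if (k > np) break
    combos <- if (k == 0L) list(integer()) else
      asplit(utils::combn(np, k), 2L)
    for (idx in combos) {
      h <- toggle_pairs(g, prs[idx, , drop = FALSE])
      if (pred(h)) {
        return(list(objective = k,
                    edits = edit_diff(g, h), graph = h))
      }
    }
  }
  stop("no edit set of size <= ", k_max, " reaches class ", cls)
}

#' Exact editing objective by exhaustive enumeration of clusterings
#'
#' Every solution graph of the three editing problems is determined by a
#' clustering (cluster editing: cliques), a clustering with per-cluster
#' optimal split editing (split cluster editing), or a shared periphery
#' plus a clustering (monopolar editing). Enumerating set partitions
#' (restricted growth strings) therefore yields the exact optimum,
#' independently of the row-generation solvers.
#'
#' @param g A `cp_graph`.
#' @param problem `"sce"`, `"me"`, or `"ce"`.
#' @param guard Maximum number of vertices accepted.
#' @return List with `objective` and `assignment` (named integer vector;
#'   `-1` marks the shared periphery for ME).
#' @export
partition_oracle <- function(g, problem = c("sce", "me", "ce"), guard = 10L) {
  problem <- match.arg(problem)
  n <- n_vertices(g)
  if (n > guard) {
    stop("partition_oracle guard: graph has more than ", guard, " vertices")
  }
  mode <- match(problem, c("sce", "me", "ce")) - 1L
  res <- partition_oracle_cpp(adjacency_matrix(g), mode)
  list(objective = as.integer(res$objective),
       assignment = stats::setNames(res$assignment, g$vertices))
}

#' Bounded search tree for split cluster editing
#'
#' Finds an edit set of size at most `k_budget` whose application yields a
#' split cluster graph, or reports that none exists. At each node a
#' forbidden induced subgraph is located by the recognizer and each of its
#' at most ten internal vertex pairs is toggled in turn; a pair edited on
#' the current branch path is never edited again, and every edit reduces
#' the budget by one.
#'
#' @param g A `cp_graph`.
#' @param k_budget Nonnegative integer.
#' @return A `cp_edit_set` (possibly empty), or `NULL` if no edit set of
#'   size at most `k_budget` suffices.
#' @export
search_tree_sce <- function(g, k_budget) {
  stopifnot(k_budget >= 0L)
  rec <- function(h, budget, touched) {
    chk <- is_split_cluster(h)
    if (chk$member) return(h)
    if (budget == 0L) return(NULL)
    prs <- all_pairs(sort(chk$certificate$vertices))
    for (i in seq_len(nrow(prs))) {
      key <- pair_key(prs[i, 1L], prs[i, 2L])
      if (key %in% touched) next
      h2 <- toggle_pairs(h, prs[i, , drop = FALSE])
      r <- rec(h2, budget - 1L, c(touched, key))
      if (!is.null(r)) return(r)
    }
    NULL
  }
  h <- rec(g, as.integer(k_budget), character())
  if (is.null(h)) NULL else edit_diff(g, h)
}

# ---------------------------------------------------------------------------
# enumeration up to isomorphism

.graph_cache <- new.env(parent = emptyenv())

canonical_key <- function(g) {
  n <- n_vertices(g)
  if (n == 0L) return("0|")
  ig <- as_igraph(g)
  perm <- igraph::canonical_permutation(ig)$labeling
  gp <- igraph::permute(ig, perm)
  el <- igraph::as_edgelist(gp, names = FALSE)
  if (nrow(el)) {
    u <- pmin(el[, 1L], el[, 2L]); v <- pmax(el[, 1L], el[, 2L])
    o <- order(u, v)
    paste0(n, "|", paste(u[o], v[o], sep = "-", collapse = ","))
  } else {
    paste0(n, "|")
  }
}

#' All graphs on exactly n vertices, up to isomorphism
#'
#' Built by extending each (n-1)-vertex representative with a new vertex
#' attached to every subset of the old vertices, deduplicating by canonical
#' form. Counts for n = 1..7: 1, 2, 4, 11, 34, 156, 1044.
#'
#' @param n Number of vertices (guarded at 7).
#' @return List of `cp_graph` objects with vertices `v1..vn`.
#' @export
enumerate_graphs <- function(n) {
  stopifnot(n >= 1L, n <= 7L)
  key <- paste0("graphs_", n)
  if (!is.null(.graph_cache[[key]])) return(.graph_cache[[key]])
  if (n == 1L) {
    out <- list(cp_graph("v1"))
  } else {
    prev <- enumerate_graphs(n - 1L)
    vs <- paste0("v", seq_len(n))
    new_v <- vs[n]
    seen <- new.env(parent = emptyenv())
    out <- list()
    for (g in prev) {
      old <- g$vertices
      for (mask in 0:(2^(n - 1L) - 1L)) {
        nbrs <- old[bitwAnd(mask, 2^(seq_len(n - 1L) - 1L)) > 0L]
        h <- cp_graph(vs, rbind(g$edges,
                                if (length(nbrs)) cbind(nbrs, new_v)))
        k <- canonical_key(h)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          out[[length(out) + 1L]] <- h
        }
      }
    }
  }
  .graph_cache[[key]] <- out
  out
}

#' Minimal forbidden induced subgraphs of a hereditary class
#'
#' Enumerates all graphs on up to `n_max` vertices up to isomorphism and
#' keeps those outside the class whose every one-vertex-deleted induced
#' subgraph is inside (which, for a hereditary class, makes every proper
#' induced subgraph a member).
#'
#' @param cls Class name as in [graph_class_predicate()].
#' @param n_max Maximum number of vertices (guarded at 7).
#' @return List of `cp_graph` objects, ordered by size.
#' @export
enumerate_minimal_forbidden <- function(cls = c("split_cluster", "monopolar", "cluster"),
                                        n_max) {
  cls <- match.arg(cls)
  stopifnot(n_max >= 1L, n_max <= 7L)
  pred <- graph_class_predicate(cls)
  out <- list()
  for (n in seq_len(n_max)) {
    for (g in enumerate_graphs(n)) {
      if (pred(g)) next
      minimal <- all(vapply(g$vertices, function(v) {
        pred(induced_subgraph(g, setdiff(g$vertices, v)))
      }, logical(1L)))
      if (minimal) out[[length(out) + 1L]] <- g
    }
  }
  out
}
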