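# Simulated-annealing heuristics for split cluster editing and monopolar
# editing. For a fixed clustering the editing cost is exact and cheap:
# edges between clusters are deleted and every cluster is repaired
# optimally -- for the split cluster model via the splittance of its
# induced degree sequence, for the monopolar model by completing clusters
# and deleting edges inside the shared periphery.

#' Annealing configuration
#'
#' @param steps Moves per restart.
#' @param t0 Initial temperature; the acceptance probability of a move
#'   worsening the objective by `delta` is `exp(-delta / T)`.
#' @param restarts Number of independent restarts; the best state over all
#'   restarts is returned.
#' @param seed Integer seed; fixed seed gives a bit-identical trajectory.
#' @param schedule `"linear"` cools as `T0 * (1 - t/steps)` (default);
#'   `"geometric"` as `T0 * alpha^t`.
#' @param alpha Decay factor for the geometric schedule.
#' @param check Debug flag: after every accepted move the incrementally
#'   maintained cost is compared against a full recomputation.
#' @return List of class `cp_anneal_cfg`.
#' @export
anneal_config <- function(steps = 20000L, t0 = 1, restarts = 100L,
                          seed = 1L, schedule = c("linear", "geometric"),
                          alpha = 0.9995, check = FALSE) {
  schedule <- match.arg(schedule)
  stopifnot(steps >= 1L, restarts >= 1L, t0 > 0)
  structure(list(steps = as.integer(steps), t0 = t0,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 schedule = schedule, alpha = alpha, check = isTRUE(check)),
            class = "cp_anneal_cfg")
}

# clustering argument: list of character vectors partitioning the vertices
check_clustering <- function(g, clustering, periphery = character()) {
  all_v <- c(unlist(clustering), periphery)
  if (anyDuplicated(all_v) || !setequal(all_v, g$vertices)) {
    stop("`clustering` (plus periphery) must partition the vertex set")
  }
  invisible(TRUE)
}

#' Split cluster editing cost of a fixed clustering
#'
#' Number of edges joining different clusters plus, for each cluster, the
#' splittance of the induced subgraph's degree sequence.
#'
#' @param g A `cp_graph`.
#' @param clustering List of character vectors partitioning the vertices.
#' @return Nonnegative integer.
#' @export
sce_cost <- function(g, clustering) {
  check_clustering(g, clustering)
  memb <- cluster_membership(clustering)
  between <- sum(memb[g$edges[, 1L]] != memb[g$edges[, 2L]])
  intra <- sum(vapply(clustering, function(cl) {
    splittance(vertex_degrees(induced_subgraph(g, cl)))
  }, integer(1L)))
  as.integer(between + intra)
}

#' Monopolar editing cost of a fixed clustering and shared periphery
#'
#' Edges inside the periphery are deleted, edges between different clusters
#' are deleted, missing pairs inside clusters are inserted;
#' periphery-cluster edges are free.
#'
#' @param g A `cp_graph`.
#' @param clustering List of character vectors (the clusters).
#' @param periphery Character vector; together with the clusters this must
#'   partition the vertices.
#' @return Nonnegative integer.
#' @export
me_cost <- function(g, clustering, periphery) {
  check_clustering(g, clustering, periphery)
  memb <- cluster_membership(clustering)
  u <- g$edges[, 1L]; v <- g$edges[, 2L]
  in_peri <- sum(u %in% periphery & v %in% periphery)
  both_cl <- !(u %in% periphery) & !(v %in% periphery)
  between <- sum(both_cl & memb[u] != memb[v])
  missing <- sum(vapply(clustering, function(cl) {
    choose(length(cl), 2L) - n_edges(induced_subgraph(g, cl))
  }, numeric(1L)))
  as.integer(in_peri + between + missing)
}

cluster_membership <- function(clustering) {
  if (length(clustering) == 0L) return(stats::setNames(integer(), character()))
  stats::setNames(rep(seq_along(clustering), lengths(clustering)),
                  unlist(clustering))
}

# shared driver over the C++ annealer; mode: 0 sce, 1 me, 2 ce
anneal_run <- function(g, mode, cfg) {
  n <- n_vertices(g)
  if (n == 0L) {
    return(list(cluster = integer(), cost = 0, restart_best = numeric()))
  }
  anneal_cpp(adjacency_matrix(g), mode, cfg$steps, cfg$restarts, cfg$t0,
             if (cfg$schedule == "linear") 0L else 1L, cfg$alpha,
             as.double(cfg$seed %% 2^31), cfg$check)
}

# ids (0-based, -1 = periphery) -> list of clusters + periphery labels
ids_to_clusters <- function(g, ids) {
  peri <- g$vertices[ids < 0L]
  rest <- ids >= 0L
  clusters <- split(g$vertices[rest], ids[rest])
  clusters <- lapply(unname(clusters), sort)
  if (length(clusters)) {
    clusters <- clusters[order(vapply(clusters, `[`, character(1L), 1L))]
  }
  list(clusters = clusters, periphery = sort(peri))
}

# realize the optimal split editing of each cluster: top-k degree vertices
# (ties lexicographic) become the clique, the rest the independent set
sce_clustering_to_solution <- function(g, clustering) {
  ins <- del <- matrix(character(), ncol = 2L)
  memb <- cluster_membership(clustering)
  if (nrow(g$edges)) {
    between <- memb[g$edges[, 1L]] != memb[g$edges[, 2L]]
    del <- g$edges[between, , drop = FALSE]
  }
  clusters <- list()
  for (cl in clustering) {
    sub <- induced_subgraph(g, cl)
    deg <- vertex_degrees(sub)
    o <- order(-deg, names(deg), method = "radix")
    d <- deg[o]
    k <- if (length(d)) max(which(d >= seq_along(d) - 1L)) else 0L
    core <- sort(names(d)[seq_len(k)])
    peri <- sort(setdiff(cl, core))
    a <- adjacency_matrix(sub)
    if (length(core) > 1L) {
      cp <- all_pairs(core)
      miss <- !a[cp]
      ins <- rbind(ins, cp[miss, , drop = FALSE])
    }
    if (length(peri) > 1L) {
      pp <- all_pairs(peri)
      pres <- a[pp]
      del <- rbind(del, pp[pres, , drop = FALSE])
    }
    clusters[[length(clusters) + 1L]] <- list(core = core, periphery = peri)
  }
  e <- edit_set(ins, del, g = g)
  list(edits = e, graph = apply_edits(g, e),
       partition = core_periphery_partition(clusters, mode = "per_cluster"))
}

# realize the monopolar editing implied by clusters + shared periphery
me_assignment_to_solution <- function(g, clustering, periphery) {
  memb <- cluster_membership(clustering)
  ins <- del <- matrix(character(), ncol = 2L)
  if (nrow(g$edges)) {
    u <- g$edges[, 1L]; v <- g$edges[, 2L]
    peri_edge <- u %in% periphery & v %in% periphery
    both_cl <- !(u %in% periphery) & !(v %in% periphery)
    between <- both_cl & memb[u] != memb[v]
    del <- g$edges[peri_edge | between, , drop = FALSE]
  }
  a <- adjacency_matrix(g)
  for (cl in clustering) {
    if (length(cl) > 1L) {
      cp <- all_pairs(sort(cl))
      ins <- rbind(ins, cp[!a[cp], , drop = FALSE])
    }
  }
  e <- edit_set(ins, del, g = g)
  h <- apply_edits(g, e)
  clusters <- lapply(clustering, function(cl) list(core = sort(cl)))
  list(edits = e, graph = h,
       partition = core_periphery_partition(clusters, mode = "shared",
                                            shared_periphery = sort(periphery),
                                            graph = h))
}

#' Simulated annealing for split cluster editing
#'
#' Starts every restart from the all-singleton clustering; each step moves
#' a uniformly chosen vertex either into the cluster of one of its
#' neighbors or into a fresh empty cluster, accepting worsening moves with
#' probability `exp(-delta/T)` under the configured cooling schedule. The
#' per-cluster core/periphery split of the returned state realizes each
#' cluster's splittance.
#'
#' @param g A `cp_graph`.
#' @param cfg An [anneal_config()].
#' @return A `cp_solve_result` with `optimal = FALSE` and the per-restart
#'   best objectives in `solver_log$restart_best`.
#' @export
anneal_sce <- function(g, cfg = anneal_config()) {
  run <- anneal_run(g, 0L, cfg)
  parts <- ids_to_clusters(g, run$cluster)
  sol <- sce_clustering_to_solution(g, parts$clusters)
  stopifnot(edit_size(sol$edits) == run$cost)
  out <- solve_result("sce", "anneal", g, sol$graph, sol$partition,
                      optimal = FALSE,
                      log = list(cfg = cfg, restart_best = run$restart_best))
  stopifnot(is_split_cluster(out$graph)$member)
  out
}

#' Simulated annealing for monopolar editing
#'
#' As [anneal_sce()], with one extra move type: a vertex may also be moved
#' into the shared periphery (and a periphery vertex back into a cluster).
#'
#' @inheritParams anneal_sce
#' @return A `cp_solve_result` in shared-periphery mode.
#' @export
anneal_me <- function(g, cfg = anneal_config()) {
  run <- anneal_run(g, 1L, cfg)
  parts <- ids_to_clusters(g, run$cluster)
  sol <- me_assignment_to_solution(g, parts$clusters, parts$periphery)
  stopifnot(edit_size(sol$edits) == run$cost)
  out <- solve_result("me", "anneal", g, sol$graph, sol$partition,
                      optimal = FALSE,
                      log = list(cfg = cfg, restart_best = run$restart_best))
  chk <- check_annotated_monopolar(
    out$graph, list(core = setdiff(g$vertices, parts$periphery),
                    periphery = parts$periphery))
  stopifnot(chk$ok)
  out
}

# cluster-editing annealer used only to warm-start the exact CE solver
anneal_ce_internal <- function(g, cfg = anneal_config()) {
  run <- anneal_run(g, 2L, cfg)
  parts <- ids_to_clusters(g, run$cluster)
  memb <- cluster_membership(parts$clusters)
  ins <- del <- matrix(character(), ncol = 2L)
  if (nrow(g$edges)) {
    between <- memb[g$edges[, 1L]] != memb[g$edges[, 2L]]
    del <- g$edges[between, , drop = FALSE]
  }
  a <- adjacency_matrix(g)
  for (cl in parts$clusters) {
    if (length(cl) > 1L) {
      cp <- all_pairs(sort(cl))
      ins <- rbind(ins, cp[!a[cp], , drop = FALSE])
    }
  }
  e <- edit_set(ins, del, g = g)
  h <- apply_edits(g, e)
  stopifnot(edit_size(e) == run$cost)
  comps <- connected_components(h)
  singles <- unlist(comps[lengths(comps) == 1L]) %||% character()
  clusters <- lapply(comps[lengths(comps) > 1L], function(comp) list(core = comp))
  solve_result("ce", "anneal", g, h,
               core_periphery_partition(clusters, mode = "shared",
                                        shared_periphery = sort(as.character(singles)),
                                        graph = g),
               optimal = FALSE, log = list(cfg = cfg))
}
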