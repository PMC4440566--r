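# Cluster statistics and protein-complex detection scoring.

#' Core-periphery partition container
#'
#' In `per_cluster` mode (split cluster model) every cluster owns its
#' periphery and the clusters partition the vertex set. In `shared` mode
#' (monopolar / cluster model) one independent set is shared; each cluster
#' is then assigned an effective periphery, the neighborhood `N(core)` of
#' its core in a reference graph.
#'
#' @param clusters List of lists with a `core` character vector and, in
#'   `per_cluster` mode, a `periphery` character vector.
#' @param mode `"per_cluster"` or `"shared"`.
#' @param shared_periphery Character vector (shared mode).
#' @param graph Optional `cp_graph` in which effective peripheries
#'   `N(core)` are computed for shared mode (typically the edited solution
#'   graph for the monopolar model, the input graph for cluster editing).
#' @return Object of class `cp_partition`.
#' @export
core_periphery_partition <- function(clusters, mode = c("per_cluster", "shared"),
                                     shared_periphery = character(),
                                     graph = NULL) {
  mode <- match.arg(mode)
  clusters <- lapply(clusters, function(cl) {
    cl$core <- sort(as.character(cl$core))
    cl$periphery <- sort(as.character(cl$periphery %||% character()))
    cl
  })
  cores <- unlist(lapply(clusters, `[[`, "core"))
  if (anyDuplicated(cores)) stop("cores must be pairwise disjoint")
  if (mode == "per_cluster") {
    allv <- c(cores, unlist(lapply(clusters, `[[`, "periphery")))
    if (anyDuplicated(allv)) stop("per-cluster vertex sets must be disjoint")
    if (length(shared_periphery)) stop("per_cluster mode has no shared periphery")
  } else if (!is.null(graph)) {
    al <- adjacency_list(graph)
    clusters <- lapply(clusters, function(cl) {
      nb <- setdiff(sort(unique(unlist(al[cl$core]))), cl$core)
      cl$periphery <- nb
      cl
    })
  }
  structure(list(clusters = clusters, mode = mode,
                 shared_periphery = sort(as.character(shared_periphery))),
            class = "cp_partition")
}

#' @export
print.cp_partition <- function(x, ...) {
  cat("<cp_partition> ", length(x$clusters), " clusters (", x$mode,
      " mode)", if (x$mode == "shared")
        paste0(", shared periphery of ", length(x$shared_periphery)),
      "\n", sep = "")
  invisible(x)
}

cluster_size <- function(cl) length(cl$core) + length(cl$periphery)

#' Filter gold-standard complexes against a subnetwork
#'
#' Three steps, in order: discard complexes with less than 50% of their
#' members in the graph, restrict the rest to members present in the
#' graph, then discard complexes left with fewer than three members.
#'
#' @param cx Named list of character vectors (see [read_complexes()]).
#' @param g A `cp_graph`.
#' @return Filtered named list.
#' @export
filter_complexes <- function(cx, g) {
  vs <- g$vertices
  kept <- list()
  for (nm in names(cx)) {
    members <- cx[[nm]]
    inside <- intersect(members, vs)
    if (length(inside) < 0.5 * length(members)) next
    if (length(inside) < 3L) next
    kept[[nm]] <- inside
  }
  kept
}

#' Nontrivial clusters of a partition
#'
#' A cluster is nontrivial if it has at least three vertices (core plus
#' effective periphery) and at least two core vertices.
#'
#' @param p A [core_periphery_partition()].
#' @return List of the nontrivial clusters.
#' @export
nontrivial_clusters <- function(p) {
  Filter(function(cl) cluster_size(cl) >= 3L && length(cl$core) >= 2L,
         p$clusters)
}

#' Complex detection report
#'
#' A complex is detected by a cluster if at least 50% of the cluster's core
#' belongs to the complex and at least 50% of the complex belongs to the
#' cluster (core plus periphery). Each complex counts once; among several
#' detecting clusters the best-scoring one (largest complex coverage, then
#' largest core purity) is reported. Percentages: `core_pct` -- core
#' vertices inside the complex; `comp_pct` -- complex members inside the
#' cluster; `extra_pct` -- periphery vertices outside the complex (0 for an
#' empty periphery).
#'
#' @param p A [core_periphery_partition()].
#' @param cx Named list of complexes, already filtered
#'   ([filter_complexes()]).
#' @return List with `per_complex` (data frame) and `summary` (detected
#'   count `D` plus mean/median of the three percentages over detected
#'   complexes).
#' @export
detect_complexes <- function(p, cx) {
  rows <- lapply(names(cx), function(nm) {
    comp <- cx[[nm]]
    best <- NULL
    for (i in seq_along(p$clusters)) {
      cl <- p$clusters[[i]]
      if (length(cl$core) == 0L) next
      cluster_v <- union(cl$core, cl$periphery)
      core_frac <- length(intersect(cl$core, comp)) / length(cl$core)
      comp_frac <- length(intersect(comp, cluster_v)) / length(comp)
      if (core_frac < 0.5 || comp_frac < 0.5) next
      extra_frac <- if (length(cl$periphery) == 0L) 0 else
        length(setdiff(cl$periphery, comp)) / length(cl$periphery)
      cand <- list(cluster = i, core_pct = 100 * core_frac,
                   comp_pct = 100 * comp_frac, extra_pct = 100 * extra_frac)
      if (is.null(best) ||
          cand$comp_pct > best$comp_pct ||
          (cand$comp_pct == best$comp_pct && cand$core_pct > best$core_pct)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      data.frame(complex = nm, detected = FALSE, cluster = NA_integer_,
                 core_pct = NA_real_, comp_pct = NA_real_,
                 extra_pct = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(complex = nm, detected = TRUE, cluster = best$cluster,
                 core_pct = best$core_pct, comp_pct = best$comp_pct,
                 extra_pct = best$extra_pct, stringsAsFactors = FALSE)
    }
  })
  per_complex <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(per_complex)) {
    per_complex <- data.frame(complex = character(), detected = logical(),
                              cluster = integer(), core_pct = numeric(),
                              comp_pct = numeric(), extra_pct = numeric())
  }
  det <- per_complex[per_complex$detected, , drop = FALSE]
  agg <- function(x, f) if (nrow(det) == 0L) NA_real_ else f(x)
  list(per_complex = per_complex,
       summary = list(
         D = nrow(det),
         core_pct_mean = agg(det$core_pct, mean),
         core_pct_median = agg(det$core_pct, stats::median),
         comp_pct_mean = agg(det$comp_pct, mean),
         comp_pct_median = agg(det$comp_pct, stats::median),
         extra_pct_mean = agg(det$extra_pct, mean),
         extra_pct_median = agg(det$extra_pct, stats::median)))
}

#' Solution statistics
#'
#' The headline columns of a solution summary: number of edge
#' modifications `k`, number of nontrivial clusters `K`, and the mean core
#' and periphery sizes over nontrivial clusters.
#'
#' @param p A [core_periphery_partition()].
#' @param edits A `cp_edit_set`, or `NULL` (then `k` is `NA`).
#' @return List with `k`, `K`, `c_bar`, `p_bar`.
#' @export
partition_stats <- function(p, edits = NULL) {
  nt <- nontrivial_clusters(p)
  list(k = if (is.null(edits)) NA_integer_ else edit_size(edits),
       K = length(nt),
       c_bar = if (length(nt)) mean(vapply(nt, function(cl) length(cl$core),
                                           numeric(1L))) else NA_real_,
       p_bar = if (length(nt)) mean(vapply(nt, function(cl) length(cl$periphery),
                                           numeric(1L))) else NA_real_)
}
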