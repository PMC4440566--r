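# Seeded generators for test instances: Erdos-Renyi graphs and planted
# core-periphery structures with controlled perturbation.

# run code under a private RNG state, restoring the caller's stream
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Erdos-Renyi random graph
#'
#' Each of the n(n-1)/2 vertex pairs is included independently with
#' probability `p`; a fixed seed reproduces the graph bit-identically.
#'
#' @param n Number of vertices (labeled `v01`, `v02`, ...).
#' @param p Edge probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [cp_graph()].
#' @export
er_graph <- function(n, p, seed = 1L) {
  stopifnot(n >= 0L, is.numeric(p), length(p) == 1L)
  if (is.na(p) || p < 0 || p > 1) stop("`p` must be in [0, 1]")
  width <- max(2L, nchar(as.character(max(n, 1L))))
  vs <- sprintf(paste0("v%0", width, "d"), seq_len(n))
  prs <- all_pairs(vs)
  keep <- local_seed(seed, stats::runif(nrow(prs)) < p)
  cp_graph(vs, prs[keep, , drop = FALSE])
}

#' Planted core-periphery instance
#'
#' Builds a noiseless graph matching one of the two structural models:
#' cores are disjoint cliques; periphery vertices form an independent set
#' attached either to their own cluster's core only (`"disjoint"`, one
#' periphery per cluster -- a split cluster graph) or to one or more cores
#' (`"shared"` -- a monopolar graph). Each periphery vertex picks core
#' vertices independently with probability `attach_prob`, redrawing until
#' it has at least one attachment (and, in the shared model, at least one
#' core).
#'
#' @param core_sizes Positive integer vector, one clique size per cluster.
#' @param periphery_sizes For `"disjoint"`: one periphery size per cluster
#'   (recycled); for `"shared"`: total size of the shared periphery.
#' @param model `"disjoint"` or `"shared"`.
#' @param attach_prob Attachment probability in (0, 1].
#' @param seed Integer seed.
#' @return List with `graph`, `truth` (a [core_periphery_partition()]),
#'   `model`, and `applied_noise` (an empty edit set; see [perturb()]).
#' @export
planted_instance <- function(core_sizes, periphery_sizes,
                             model = c("disjoint", "shared"),
                             attach_prob = 0.5, seed = 1L) {
  model <- match.arg(model)
  stopifnot(all(core_sizes >= 1L), attach_prob > 0, attach_prob <= 1)
  nc <- length(core_sizes)
  cores <- lapply(seq_len(nc), function(i) {
    sprintf("c%02d_%02d", i, seq_len(core_sizes[i]))
  })
  edges <- do.call(rbind, c(list(matrix(character(), ncol = 2L)),
                            lapply(cores, function(cl) all_pairs(cl))))
  local_seed(seed, {
    if (model == "disjoint") {
      stopifnot(all(periphery_sizes >= 0L))
      periphery_sizes <- rep_len(periphery_sizes, nc)
      peris <- lapply(seq_len(nc), function(i) {
        if (periphery_sizes[i] == 0L) character() else
          sprintf("p%02d_%02d", i, seq_len(periphery_sizes[i]))
      })
      for (i in seq_len(nc)) {
        for (pv in peris[[i]]) {
          repeat {
            sel <- stats::runif(core_sizes[i]) < attach_prob
            if (any(sel)) break
          }
          edges <- rbind(edges, cbind(cores[[i]][sel], pv))
        }
      }
      g <- cp_graph(unlist(c(cores, peris)), edges)
      truth <- core_periphery_partition(
        lapply(seq_len(nc), function(i) list(core = cores[[i]],
                                             periphery = peris[[i]])),
        mode = "per_cluster")
      stopifnot(is_split_cluster(g)$member)
    } else {
      np <- sum(periphery_sizes)
      peri <- if (np == 0L) character() else sprintf("s_%02d", seq_len(np))
      for (pv in peri) {
        repeat {
          which_cores <- stats::runif(nc) < attach_prob
          if (any(which_cores)) break
        }
        for (i in which(which_cores)) {
          repeat {
            sel <- stats::runif(core_sizes[i]) < attach_prob
            if (any(sel)) break
          }
          edges <- rbind(edges, cbind(cores[[i]][sel], pv))
        }
      }
      g <- cp_graph(c(unlist(cores), peri), edges)
      truth <- core_periphery_partition(
        lapply(cores, function(cl) list(core = cl)),
        mode = "shared", shared_periphery = peri, graph = g)
      chk <- check_annotated_monopolar(
        g, list(core = unlist(cores), periphery = peri))
      stopifnot(chk$ok)
    }
    list(graph = g, truth = truth, model = model,
         applied_noise = edit_set())
  })
}

#' Toggle a fixed number of uniformly chosen vertex pairs
#'
#' `num_edits` distinct pairs are drawn without replacement and each is
#' flipped (inserted if absent, deleted if present).
#'
#' @param g A `cp_graph`.
#' @param num_edits Number of pairs to toggle.
#' @param seed Integer seed.
#' @return List with `graph` (perturbed) and `edits` (the applied
#'   `cp_edit_set`; applying it to the perturbed graph restores `g`).
#' @export
perturb <- function(g, num_edits, seed = 1L) {
  prs <- all_pairs(g$vertices)
  stopifnot(num_edits >= 0L, num_edits <= nrow(prs))
  if (num_edits == 0L) {
    return(list(graph = g, edits = edit_set()))
  }
  idx <- local_seed(seed, sample.int(nrow(prs), num_edits))
  sel <- prs[idx, , drop = FALSE]
  h <- toggle_pairs(g, sel)
  list(graph = h, edits = edit_diff(g, h))
}
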