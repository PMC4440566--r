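# Exact solvers for split cluster editing (SCE), monopolar editing (ME),
# and cluster editing (CE).
#
# All three are expressed over binary variables e_uv (edge present in the
# solution graph) and, for the partition formulations, c_u (vertex is a
# core vertex), minimizing the number of e variables that differ from the
# input graph. Constraint rows are generated lazily: the relaxed system is
# solved to optimality, the candidate solution graph is handed to the
# matching recognizer, and every forbidden structure it reports contributes
# a new row until the recognizer accepts. Row families:
#
#   forbidden subgraph (SCE):  sum over pairs inside a forbidden induced
#       subgraph of the literals "differ from the pattern" >= 1; for a C5
#       the right-hand side can be raised to 2, and a P5 u-v-w-x-y admits
#       the strengthened inequality with 1/2-coefficients on the insertions
#       that themselves create a new forbidden subgraph (e_uy omitted).
#   independent set:  c_u + c_v + (1 - e_uv) >= 1 for every pair.
#   P3 (SCE):  (1-e_uv) + (1-e_vw) + e_uw + (1-c_u) + (1-c_w) >= 1.
#   P3 (ME):   additionally (1-c_v), so only core-only P3s are forbidden.
#   P3 (CE):   (1-e_uv) + (1-e_vw) + e_uw >= 1.

# ---------------------------------------------------------------------------
# model container

#' Build an editing model for a graph
#'
#' Creates the variable layout (one binary edge variable per unordered
#' vertex pair and, for partition formulations, one binary core variable
#' per vertex) plus the initial constraint rows of the chosen formulation.
#'
#' @param g A `cp_graph`.
#' @param formulation One of `"sce_forbidden"`, `"sce_partition"`,
#'   `"me_partition"`, `"ce"`.
#' @return Object of class `cp_ilp_model`: variable names, base values
#'   (the input graph), per-variable costs, fixed assignments (`NA` =
#'   free), and a list of rows.
#' @export
ilp_model <- function(g, formulation = c("sce_forbidden", "sce_partition",
                                         "me_partition", "ce")) {
  formulation <- match.arg(formulation)
  pairs <- all_pairs(g$vertices)
  pk <- if (nrow(pairs)) paste(pairs[, 1L], pairs[, 2L], sep = "\t") else character()
  e_names <- if (length(pk)) paste0("e:", pk) else character()
  has_c <- formulation %in% c("sce_partition", "me_partition")
  c_names <- if (has_c) paste0("c:", g$vertices) else character()
  var_names <- c(e_names, c_names)
  base <- c(as.integer(pk %in% edge_keys(g)), rep(1L, length(c_names)))
  cost <- c(rep(1, length(e_names)), rep(0, length(c_names)))
  m <- structure(list(
    formulation = formulation, g = g, pairs = pairs,
    var_names = var_names, var_index = stats::setNames(seq_along(var_names), var_names),
    base = base, cost = cost,
    fixed = rep(NA_integer_, length(var_names)),
    rows = list()
  ), class = "cp_ilp_model")
  if (formulation %in% c("sce_partition", "me_partition")) {
    m <- add_independent_set_rows(m)
    m <- add_input_p3_rows(m)
  }
  if (formulation == "ce") {
    m <- add_input_p3_rows(m)
  }
  m
}

#' @export
print.cp_ilp_model <- function(x, ...) {
  cat("<cp_ilp_model> ", x$formulation, ": ", length(x$var_names),
      " variables, ", length(x$rows), " rows, ",
      sum(!is.na(x$fixed)), " fixed\n", sep = "")
  invisible(x)
}

e_var <- function(m, u, v) m$var_index[[paste0("e:", pair_key(u, v))]]
c_var <- function(m, u) m$var_index[[paste0("c:", u)]]

new_row <- function(var, want, coef, rhs, tag) {
  list(var = as.integer(var), want = as.integer(want),
       coef = as.numeric(coef), rhs = as.numeric(rhs), tag = tag)
}

row_signature <- function(row) {
  o <- order(row$var)
  paste(c(row$var[o], row$want[o], row$coef[o], row$rhs), collapse = ",")
}

add_rows <- function(m, rows) {
  sigs <- vapply(m$rows, row_signature, character(1L))
  for (row in rows) {
    s <- row_signature(row)
    if (!(s %in% sigs)) {
      m$rows[[length(m$rows) + 1L]] <- row
      sigs <- c(sigs, s)
    }
  }
  m
}

# constraint (independent set): periphery vertices may not be adjacent
add_independent_set_rows <- function(m) {
  pairs <- m$pairs
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    u <- pairs[i, 1L]; v <- pairs[i, 2L]
    new_row(c(c_var(m, u), c_var(m, v), e_var(m, u, v)),
            c(1L, 1L, 0L), c(1, 1, 1), 1, "indep")
  })
  add_rows(m, rows)
}

# P3 rows (by formulation) for the triples inducing a P3 in the input graph
add_input_p3_rows <- function(m) {
  add_rows(m, lapply(induced_p3s(m$g), function(t3) {
    p3_row(m, t3[1L], t3[2L], t3[3L])
  }))
}

# ordered triples (u, v, w), v the middle vertex, u < w, inducing a P3
induced_p3s <- function(g, cap = Inf) {
  a <- adjacency_matrix(g)
  al <- adjacency_list(g)
  out <- list()
  for (v in g$vertices) {
    nb <- al[[v]]
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) {
      for (j in seq(i + 1L, length(nb))) {
        if (!a[nb[i], nb[j]]) {
          out[[length(out) + 1L]] <- c(nb[i], v, nb[j])
          if (length(out) >= cap) return(out)
        }
      }
    }
  }
  out
}

# one P3 row for the triple u-v-w (v middle) in the current formulation
p3_row <- function(m, u, v, w) {
  var <- c(e_var(m, u, v), e_var(m, v, w), e_var(m, u, w))
  want <- c(0L, 0L, 1L)
  coef <- c(1, 1, 1)
  if (m$formulation == "sce_partition") {
    var <- c(var, c_var(m, u), c_var(m, w))
    want <- c(want, 0L, 0L)
    coef <- c(coef, 1, 1)
  } else if (m$formulation == "me_partition") {
    var <- c(var, c_var(m, u), c_var(m, v), c_var(m, w))
    want <- c(want, 0L, 0L, 0L)
    coef <- c(coef, 1, 1, 1)
  }
  new_row(var, want, coef, 1, "P3")
}

# forbidden-subgraph row: at least `rhs` of the pairs inside the vertex set
# must differ from how the graph h currently has them
forbidden_row <- function(m, h, vertices, rhs = 1, tag = "forbidden") {
  prs <- all_pairs(sort(vertices))
  hk <- edge_keys(h)
  var <- integer(0); want <- integer(0)
  for (i in seq_len(nrow(prs))) {
    u <- prs[i, 1L]; v <- prs[i, 2L]
    var <- c(var, e_var(m, u, v))
    want <- c(want, 1L - as.integer(pair_key(u, v) %in% hk))
  }
  new_row(var, want, rep(1, length(var)), rhs, tag)
}

# strengthened P5 inequality for the path u-v-w-x-y: deleting a path edge
# counts 1, inserting a chord that leaves another forbidden subgraph counts
# only 1/2, and the end-to-end insertion (which creates a C5) is omitted
p5_strengthened_row <- function(m, p5) {
  u <- p5[1L]; v <- p5[2L]; w <- p5[3L]; x <- p5[4L]; y <- p5[5L]
  var <- c(e_var(m, u, v), e_var(m, v, w), e_var(m, w, x), e_var(m, x, y),
           e_var(m, u, w), e_var(m, v, x), e_var(m, w, y),
           e_var(m, x, u), e_var(m, y, v))
  want <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L)
  coef <- c(1, 1, 1, 1, 0.5, 1, 0.5, 0.5, 0.5)
  new_row(var, want, coef, 1, "P5cut")
}

#' Fix variables using the degree-one periphery rule
#'
#' In the partition formulation for split cluster editing there is always
#' an optimal solution in which a degree-one vertex whose sole neighbor has
#' degree greater than one is a periphery vertex with no inserted edges:
#' for each such vertex `u` with neighbor `v`, `c_u` is fixed to 0 and
#' `e_uw` to 0 for every `w` outside `{u, v}`.
#'
#' @param g The input `cp_graph` the model was built for.
#' @param m A `cp_ilp_model` with core variables.
#' @return The model with updated fixed assignments.
#' @export
fix_variables_obs1 <- function(g, m) {
  stopifnot(inherits(m, "cp_ilp_model"),
            m$formulation %in% c("sce_partition", "me_partition"))
  deg <- vertex_degrees(g)
  al <- adjacency_list(g)
  for (u in g$vertices[deg == 1L]) {
    v <- al[[u]][1L]
    if (deg[[v]] <= 1L) next
    m$fixed[c_var(m, u)] <- 0L
    for (w in setdiff(g$vertices, c(u, v))) {
      m$fixed[e_var(m, u, w)] <- 0L
    }
  }
  m
}

# ---------------------------------------------------------------------------
# solver configuration and result container

#' Configuration for the exact solvers
#'
#' @param cuts Add strengthened rows (C5 right-hand side 2 and the 1/2
#'   coefficient P5 inequality) in the forbidden-subgraph formulation.
#' @param warm_start Seed the search with the annealing heuristic solution
#'   (10 restarts) as upper bound and incumbent.
#' @param fix_degree_one Apply the degree-one periphery rule
#'   ([fix_variables_obs1()]) in the SCE partition formulation.
#' @param seed Integer seed for the warm-start heuristic.
#' @param node_limit Branch-and-bound node budget; when exhausted the best
#'   known solution is returned with `optimal = FALSE`.
#' @param max_rounds Cap on row-generation rounds.
#' @param warm_steps,warm_restarts Annealing schedule of the warm start.
#' @return A list of class `cp_solve_cfg`.
#' @export
solve_cfg <- function(cuts = TRUE, warm_start = TRUE, fix_degree_one = TRUE,
                      seed = 1L, node_limit = 5e7, max_rounds = 1000L,
                      warm_steps = 20000L, warm_restarts = 10L) {
  structure(list(cuts = cuts, warm_start = warm_start,
                 fix_degree_one = fix_degree_one, seed = as.integer(seed),
                 node_limit = node_limit, max_rounds = as.integer(max_rounds),
                 warm_steps = as.integer(warm_steps),
                 warm_restarts = as.integer(warm_restarts)),
            class = "cp_solve_cfg")
}

solve_result <- function(problem, method, g, edited, partition, optimal, log) {
  edits <- edit_diff(g, edited)
  structure(list(problem = problem, method = method,
                 edits = edits, objective = edit_size(edits),
                 graph = edited, partition = partition,
                 optimal = optimal, solver_log = log),
            class = "cp_solve_result")
}

#' @export
print.cp_solve_result <- function(x, ...) {
  cat("<cp_solve_result> ", x$problem, " (", x$method, "): objective ",
      x$objective, if (x$optimal) " (optimal)" else " (heuristic/bounded)",
      "\n", sep = "")
  invisible(x)
}

# run the C++ branch and bound on the current rows of a model
solve_model <- function(m, start = NULL, start_is_incumbent = TRUE,
                        node_limit = 5e7, ub_only = FALSE) {
  nvar <- length(m$var_names)
  res <- cover_branch_solve_cpp(
    nvar, m$base, m$cost,
    ifelse(is.na(m$fixed), -1L, m$fixed),
    lapply(m$rows, function(r) r$var - 1L),
    lapply(m$rows, function(r) r$want),
    lapply(m$rows, function(r) r$coef),
    vapply(m$rows, function(r) r$rhs, numeric(1L)),
    if (is.null(start)) NULL else as.integer(start),
    if (start_is_incumbent) 1 else 0,
    node_limit)
  res
}

# solution graph implied by a variable assignment
assignment_graph <- function(m, values) {
  ne <- nrow(m$pairs)
  keep <- values[seq_len(ne)] == 1L
  cp_graph(m$g$vertices, m$pairs[keep, , drop = FALSE])
}

# core set implied by a variable assignment (partition formulations)
assignment_core <- function(m, values) {
  ne <- nrow(m$pairs)
  m$g$vertices[values[-seq_len(ne)] == 1L]
}

# assignment (e then c) encoding a solution graph plus optional core set
graph_assignment <- function(m, h, core = NULL) {
  ne <- nrow(m$pairs)
  pk <- if (ne) paste(m$pairs[, 1L], m$pairs[, 2L], sep = "\t") else character()
  vals <- as.integer(pk %in% edge_keys(h))
  if (length(m$var_names) > ne) {
    vals <- c(vals, as.integer(m$g$vertices %in% core))
  }
  vals
}

assignment_respects_fixed <- function(m, values) {
  idx <- which(!is.na(m$fixed))
  length(idx) == 0L || all(values[idx] == m$fixed[idx])
}

# warm start: heuristic solution after a few annealing restarts, as in the
# reference setup ("heuristic solution found after 10 rounds as MIP start")
warm_start_values <- function(m, problem, cfg) {
  acfg <- anneal_config(steps = cfg$warm_steps, restarts = cfg$warm_restarts,
                        seed = cfg$seed)
  h <- switch(problem,
              sce = anneal_sce(m$g, acfg),
              me = anneal_me(m$g, acfg),
              ce = anneal_ce_internal(m$g, acfg))
  core <- switch(problem,
                 sce = unlist(lapply(h$partition$clusters, `[[`, "core")),
                 me = unlist(lapply(h$partition$clusters, `[[`, "core")),
                 ce = NULL)
  list(values = graph_assignment(m, h$graph, core), cost = h$objective)
}

# ---------------------------------------------------------------------------
# the four solvers

#' Exact split cluster editing via the forbidden-subgraph formulation
#'
#' Row generation over edge variables only: solve, hand the candidate graph
#' to [is_split_cluster()], add a row per reported forbidden subgraph
#' (iteratively removing one certificate vertex to harvest up to n rows per
#' round), and repeat until the recognizer accepts. With `cfg$cuts`, C5
#' rows get right-hand side 2 and P5 certificates also contribute the
#' strengthened 1/2-coefficient inequality.
#'
#' @param g A `cp_graph`.
#' @param cfg A [solve_cfg()].
#' @return A `cp_solve_result` with the edit set, the edited graph, the
#'   per-cluster core/periphery partition, and solver provenance.
#' @examples
#' c5 <- cp_graph(edges = cbind(letters[1:5], letters[c(2:5, 1)]))
#' solve_sce_forbidden(c5)$objective  # 2
#' @export
solve_sce_forbidden <- function(g, cfg = solve_cfg()) {
  m <- ilp_model(g, "sce_forbidden")
  run_row_generation(
    m, problem = "sce", cfg = cfg, method = "ilp_forbidden",
    accept = function(h, values) is_split_cluster(h)$member,
    new_rows = function(m, h, values) sce_forbidden_rows(m, h, cfg),
    build_partition = function(h, values) {
      core_periphery_partition(split_cluster_partition(h), mode = "per_cluster")
    })
}

# up to n forbidden-subgraph rows: find a certificate, record it, drop one
# of its vertices, and search the remainder again
sce_forbidden_rows <- function(m, h, cfg) {
  rows <- list()
  sub <- h
  for (i in seq_len(n_vertices(h))) {
    rec <- is_split_cluster(sub)
    if (rec$member) break
    cert <- rec$certificate
    rhs <- if (cfg$cuts && cert$kind == "C5") 2 else 1
    rows[[length(rows) + 1L]] <- forbidden_row(m, h, cert$vertices, rhs = rhs,
                                               tag = cert$kind)
    if (cfg$cuts && cert$kind == "P5") {
      rows[[length(rows) + 1L]] <- p5_strengthened_row(m, cert$vertices)
    }
    sub <- induced_subgraph(sub, setdiff(sub$vertices, cert$vertices[1L]))
  }
  rows
}

#' Exact split cluster editing via the partition formulation
#'
#' Binary core indicators plus edge variables; all independent-set rows and
#' the input graph's P3 rows are present from the start, and P3 rows
#' violated by a candidate solution (an induced P3 of the solution graph
#' with both endpoints labeled core) are added lazily. The degree-one
#' periphery rule fixes variables up front.
#'
#' @inheritParams solve_sce_forbidden
#' @return A `cp_solve_result`.
#' @export
solve_sce_partition <- function(g, cfg = solve_cfg()) {
  m <- ilp_model(g, "sce_partition")
  if (cfg$fix_degree_one) m <- fix_variables_obs1(g, m)
  run_row_generation(
    m, problem = "sce", cfg = cfg, method = "ilp_partition",
    accept = function(h, values) {
      C <- assignment_core(m, values)
      check_annotated_split_cluster(
        h, list(core = C, periphery = setdiff(h$vertices, C)))$ok
    },
    new_rows = function(m, h, values) violated_p3_rows(m, h, values),
    build_partition = function(h, values) {
      C <- assignment_core(m, values)
      clusters <- lapply(connected_components(h), function(comp) {
        list(core = sort(intersect(comp, C)),
             periphery = sort(setdiff(comp, C)))
      })
      core_periphery_partition(clusters, mode = "per_cluster")
    })
}

#' Exact monopolar editing via the partition formulation
#'
#' As [solve_sce_partition()], with the P3 rows also carrying the middle
#' vertex's core indicator, so that only P3s entirely inside the core part
#' are forbidden; the result is a monopolar partition whose core part
#' induces a cluster graph and whose periphery is a shared independent set.
#'
#' @inheritParams solve_sce_forbidden
#' @return A `cp_solve_result` (partition in shared-periphery mode).
#' @export
solve_me_partition <- function(g, cfg = solve_cfg()) {
  m <- ilp_model(g, "me_partition")
  run_row_generation(
    m, problem = "me", cfg = cfg, method = "ilp_partition",
    accept = function(h, values) {
      C <- assignment_core(m, values)
      check_annotated_monopolar(
        h, list(core = C, periphery = setdiff(h$vertices, C)))$ok
    },
    new_rows = function(m, h, values) violated_p3_rows(m, h, values),
    build_partition = function(h, values) {
      C <- assignment_core(m, values)
      clusters <- lapply(connected_components(induced_subgraph(h, C)),
                        function(comp) list(core = comp))
      core_periphery_partition(clusters, mode = "shared",
                               shared_periphery = sort(setdiff(h$vertices, C)),
                               graph = h)
    })
}

#' Exact cluster editing via P3 row generation
#'
#' Edge variables only; a row per induced P3 of the input graph up front,
#' then rows for P3s of candidate solutions until the solution is a cluster
#' graph. Size-1 clusters of the result are reported as a shared periphery.
#'
#' @inheritParams solve_sce_forbidden
#' @return A `cp_solve_result` (partition in shared-periphery mode; the
#'   effective periphery of each cluster is its neighborhood in the input
#'   graph, where the edited graph would leave it empty).
#' @export
solve_ce <- function(g, cfg = solve_cfg()) {
  m <- ilp_model(g, "ce")
  run_row_generation(
    m, problem = "ce", cfg = cfg, method = "ilp_p3",
    accept = function(h, values) is_cluster_graph(h)$member,
    new_rows = function(m, h, values) {
      lapply(induced_p3s(h, cap = 2L * n_vertices(h) + 10L),
             function(t3) p3_row(m, t3[1L], t3[2L], t3[3L]))
    },
    build_partition = function(h, values) {
      comps <- connected_components(h)
      singles <- unlist(comps[vapply(comps, length, integer(1L)) == 1L])
      clusters <- lapply(comps[vapply(comps, length, integer(1L)) > 1L],
                        function(comp) list(core = comp))
      core_periphery_partition(clusters, mode = "shared",
                               shared_periphery = sort(as.character(singles %||% character())),
                               graph = g)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# P3 rows of the current formulation violated by the candidate solution:
# induced P3s of the solution graph whose required core labels are all set
violated_p3_rows <- function(m, h, values) {
  C <- assignment_core(m, values)
  rows <- list()
  for (t3 in induced_p3s(h, cap = Inf)) {
    endpoints_core <- t3[1L] %in% C && t3[3L] %in% C
    mid_core <- t3[2L] %in% C
    viol <- if (m$formulation == "me_partition") {
      endpoints_core && mid_core
    } else {
      endpoints_core
    }
    if (viol) rows[[length(rows) + 1L]] <- p3_row(m, t3[1L], t3[2L], t3[3L])
    if (length(rows) >= 2L * n_vertices(h) + 10L) break
  }
  rows
}

# shared row-generation driver
run_row_generation <- function(m, problem, cfg, method, accept, new_rows,
                               build_partition) {
  g <- m$g
  if (n_vertices(g) == 0L) {
    return(solve_result(problem, method, g, g,
                        build_partition(g, graph_assignment(m, g, character())),
                        optimal = TRUE, log = list(rounds = 0L, rows = 0L)))
  }
  start <- NULL; incumbent <- TRUE; warm_cost <- NA_real_
  if (cfg$warm_start) {
    ws <- warm_start_values(m, problem, cfg)
    start <- ws$values
    warm_cost <- ws$cost
    incumbent <- assignment_respects_fixed(m, start)
  }
  rounds <- 0L
  optimal <- TRUE
  nodes <- 0
  repeat {
    rounds <- rounds + 1L
    res <- solve_model(m, start = start, start_is_incumbent = incumbent,
                       node_limit = cfg$node_limit)
    nodes <- nodes + res$nodes
    h <- assignment_graph(m, res$values)
    if (!res$optimal) optimal <- FALSE
    if (accept(h, res$values)) break
    if (rounds >= cfg$max_rounds) {
      optimal <- FALSE
      break
    }
    nr <- new_rows(m, h, res$values)
    before <- length(m$rows)
    m <- add_rows(m, nr)
    if (length(m$rows) == before) {
      stop("row generation stalled: recognizer rejects but no new rows found")
    }
  }
  partition <- build_partition(h, res$values)
  out <- solve_result(problem, method, g, h, partition, optimal,
                      log = list(formulation = m$formulation, rounds = rounds,
                                 rows = length(m$rows), nodes = nodes,
                                 warm_start_cost = warm_cost,
                                 cuts = cfg$cuts))
  stopifnot(out$objective == res$objective)
  out
}
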