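# Cutting-plane separation for fractional points of the editing
# formulations. Given fractional values for the edge (and core) variables,
# inequalities of a requested family that are violated by at least a
# threshold are returned, most violated first. Candidate vertex tuples are
# enumerated from the support graph -- the pairs whose edge value is
# positive -- rather than from all O(n^5) tuples.

#' Separate violated cutting planes at a fractional point
#'
#' Families: `P3` -- the partition-formulation P3 rows (endpoint core
#' indicators for SCE, all three for ME); `C4` / `P5` -- forbidden-subgraph
#' rows for split cluster editing (the P5 family uses the strengthened
#' 1/2-coefficient inequality); `W4` -- the wheel row for monopolar
#' editing. A returned cut is a list with `terms` (data frame: `var`
#' (`"e"` or `"c"`), `u`, `v`, `want`, `coef`), `rhs`, `violation`, `kind`
#' and `vertices`; its left-hand side at a point assigns each term
#' `coef * x` when `want == 1` and `coef * (1 - x)` when `want == 0`.
#'
#' @param g The input `cp_graph` (defines the variable universe).
#' @param e_values Symmetric numeric matrix in `[0, 1]` with vertex labels
#'   as dimnames: fractional edge-variable values.
#' @param c_values Named numeric vector of core-variable values (needed
#'   for the `P3` family).
#' @param kind `"P3"`, `"C4"`, `"P5"`, or `"W4"`.
#' @param problem `"sce"` or `"me"` (selects the P3 row flavor).
#' @param max_cuts Keep at most this many cuts.
#' @param min_violation Keep only cuts violated by at least this much.
#' @return List of cuts, sorted by decreasing violation.
#' @export
separate_cuts <- function(g, e_values, c_values = NULL,
                          kind = c("P3", "C4", "P5", "W4"),
                          problem = c("sce", "me"),
                          max_cuts = 500L, min_violation = 0.3) {
  kind <- match.arg(kind)
  problem <- match.arg(problem)
  vs <- g$vertices
  stopifnot(is.matrix(e_values), all(vs %in% rownames(e_values)))
  if (kind == "P3" && is.null(c_values)) {
    stop("`c_values` is required for the P3 family")
  }
  supp <- lapply(stats::setNames(vs, vs), function(u) {
    vs[e_values[u, vs] > 1e-9 & vs != u]
  })
  cuts <- switch(kind,
                 P3 = p3_cuts(vs, supp, e_values, c_values, problem),
                 C4 = c4_cuts(vs, supp, e_values),
                 P5 = p5_cuts(vs, supp, e_values),
                 W4 = w4_cuts(vs, supp, e_values))
  cuts <- Filter(function(ct) ct$violation >= min_violation - 1e-9, cuts)
  if (length(cuts) > 1L) {
    cuts <- cuts[order(vapply(cuts, `[[`, numeric(1L), "violation"),
                       decreasing = TRUE)]
  }
  if (length(cuts) > max_cuts) cuts <- cuts[seq_len(max_cuts)]
  cuts
}

cut_terms <- function(var, u, v, want, coef) {
  data.frame(var = var, u = u, v = v, want = want, coef = coef,
             stringsAsFactors = FALSE)
}

# evaluate a cut's left-hand side at the fractional point
cut_lhs <- function(ct, e_values, c_values = NULL) {
  s <- 0
  for (i in seq_len(nrow(ct$terms))) {
    t1 <- ct$terms[i, ]
    x <- if (t1$var == "e") e_values[t1$u, t1$v] else c_values[[t1$u]]
    s <- s + t1$coef * if (t1$want == 1) x else 1 - x
  }
  s
}

make_cut <- function(kind, vertices, terms, rhs, e_values, c_values = NULL) {
  ct <- list(kind = kind, vertices = vertices, terms = terms, rhs = rhs)
  ct$violation <- rhs - cut_lhs(ct, e_values, c_values)
  ct
}

p3_cuts <- function(vs, supp, e_values, c_values, problem) {
  out <- list()
  for (v in vs) {
    nb <- supp[[v]]
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) {
      for (j in seq(i + 1L, length(nb))) {
        u <- nb[i]; w <- nb[j]
        terms <- rbind(
          cut_terms("e", c(u, v, u), c(v, w, w), c(0L, 0L, 1L), c(1, 1, 1)),
          cut_terms("c", c(u, w), NA_character_, c(0L, 0L), c(1, 1)),
          if (problem == "me") cut_terms("c", v, NA_character_, 0L, 1))
        out[[length(out) + 1L]] <-
          make_cut("P3", c(u, v, w), terms, 1, e_values, c_values)
      }
    }
  }
  out
}

# forbidden-subgraph row over the pairs inside `vertices`: pattern edges
# enter negated, pattern non-edges positively
pattern_cut <- function(kind, vertices, pattern_edges, e_values) {
  prs <- all_pairs(sort(vertices))
  pk <- paste(prs[, 1L], prs[, 2L], sep = "\t")
  ek <- pair_key(pattern_edges[, 1L], pattern_edges[, 2L])
  want <- ifelse(pk %in% ek, 0L, 1L)
  terms <- cut_terms("e", prs[, 1L], prs[, 2L], want, rep(1, length(pk)))
  make_cut(kind, vertices, terms, 1, e_values)
}

c4_cuts <- function(vs, supp, e_values) {
  out <- list(); seen <- character()
  for (u in vs) {
    for (w in vs) {
      if (w <= u) next
      common <- intersect(supp[[u]], supp[[w]])
      common <- setdiff(common, c(u, w))
      if (length(common) < 2L) next
      for (i in seq_len(length(common) - 1L)) {
        for (j in seq(i + 1L, length(common))) {
          quad <- c(u, common[i], w, common[j])
          key <- paste(sort(quad), collapse = "|")
          sig <- paste(key, pair_key(u, w))  # diagonal identifies the cycle
          if (sig %in% seen) next
          seen <- c(seen, sig)
          cyc <- rbind(c(u, common[i]), c(common[i], w),
                       c(w, common[j]), c(common[j], u))
          out[[length(out) + 1L]] <- pattern_cut("C4", quad, cyc, e_values)
        }
      }
    }
  }
  out
}

# strengthened P5 inequality (1/2 coefficients; end-pair insertion omitted)
p5_cuts <- function(vs, supp, e_values) {
  out <- list(); seen <- character()
  paths <- support_paths(supp, 5L)
  for (p in paths) {
    key <- paste(p, collapse = "|")
    rkey <- paste(rev(p), collapse = "|")
    if (key %in% seen || rkey %in% seen) next
    seen <- c(seen, key)
    u <- p[1L]; v <- p[2L]; w <- p[3L]; x <- p[4L]; y <- p[5L]
    terms <- rbind(
      cut_terms("e", c(u, v, w, x), c(v, w, x, y), rep(0L, 4L), rep(1, 4L)),
      cut_terms("e", c(u, v, w, x, y), c(w, x, y, u, v),
                rep(1L, 5L), c(0.5, 1, 0.5, 0.5, 0.5)))
    out[[length(out) + 1L]] <- make_cut("P5", p, terms, 1, e_values)
  }
  out
}

# simple DFS enumeration of vertex-distinct paths in the support graph
support_paths <- function(supp, len) {
  out <- list()
  walk <- function(path) {
    if (length(path) == len) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (nxt in supp[[path[length(path)]]]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  for (s in names(supp)) walk(s)
  out
}

w4_cuts <- function(vs, supp, e_values) {
  out <- list(); seen <- character()
  for (h in vs) {
    rim <- supp[[h]]
    if (length(rim) < 4L) next
    idx <- utils::combn(length(rim), 4L)
    for (k in seq_len(ncol(idx))) {
      four <- rim[idx[, k]]
      # 4-cycles within the support graph on `four`
      perms <- list(four, four[c(1L, 2L, 4L, 3L)], four[c(1L, 3L, 2L, 4L)])
      for (cyc4 in perms) {
        ok <- all(e_values[cbind(cyc4, cyc4[c(2L, 3L, 4L, 1L)])] > 1e-9)
        if (!ok) next
        sig <- paste(h, paste(sort(four), collapse = "|"),
                     pair_key(cyc4[1L], cyc4[3L]))
        if (sig %in% seen) next
        seen <- c(seen, sig)
        pat <- rbind(cbind(cyc4, cyc4[c(2L, 3L, 4L, 1L)]),
                     cbind(cyc4, h))
        out[[length(out) + 1L]] <-
          pattern_cut("W4", c(cyc4, h), pat, e_values)
      }
    }
  }
  out
}
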