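# Separation of cutting planes at fractional points, and validity of every
# cut family against exhaustively enumerated integral solutions.

frac_point <- function(g, e_default = 0) {
  vs <- g$vertices
  m <- matrix(e_default, length(vs), length(vs), dimnames = list(vs, vs))
  diag(m) <- 0
  m
}

test_that("integral model-satisfying points yield no violated cuts", {
  g <- path_graph(3L)
  ev <- frac_point(g)
  ev["a", "b"] <- ev["b", "a"] <- 1   # keep a-b, drop b-c: a cluster graph
  cv <- c(a = 1, b = 1, c = 0)
  for (kind in c("P3", "C4", "P5", "W4")) {
    cuts <- separate_cuts(g, ev, cv, kind = kind, problem = "sce")
    expect_length(cuts, 0L)
  }
})

test_that("a core-endpoint P3 produces a fully violated partition cut", {
  g <- path_graph(3L)
  ev <- frac_point(g)
  ev["a", "b"] <- ev["b", "a"] <- 1
  ev["b", "c"] <- ev["c", "b"] <- 1
  cv <- c(a = 1, b = 0, c = 1)
  cuts <- separate_cuts(g, ev, cv, kind = "P3", problem = "sce")
  expect_length(cuts, 1L)
  expect_equal(cuts[[1L]]$violation, 1)
  expect_setequal(cuts[[1L]]$vertices, c("a", "b", "c"))
  # under the monopolar row the periphery middle vertex lifts the violation
  cuts_me <- separate_cuts(g, ev, cv, kind = "P3", problem = "me")
  expect_length(cuts_me, 0L)
})

test_that("C4 cut violation at the uniform half point matches arithmetic", {
  g <- cycle_graph(4L)
  ev <- frac_point(g, 0.5)
  cuts <- separate_cuts(g, ev, kind = "C4", min_violation = -10)
  expect_gte(length(cuts), 1L)
  # lhs = 4 * (1 - 0.5) + 2 * 0.5 = 3, so the violation is 1 - 3 = -2
  expect_equal(cuts[[1L]]$violation, -2)
  expect_length(separate_cuts(g, ev, kind = "C4", min_violation = 0.3), 0L)
})

test_that("max_cuts and min_violation truncate and order the cut pool", {
  g <- complete_graph(5L)
  ev <- frac_point(g, 1e-3)  # weak support everywhere: cuts nearly fully violated
  cuts <- separate_cuts(g, ev, kind = "C4", min_violation = 0.3, max_cuts = 7L)
  expect_lte(length(cuts), 7L)
  v <- vapply(cuts, `[[`, numeric(1L), "violation")
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 0.3))
})

# enumerate all labeled graphs on the vertex set of g (and, for partition
# rows, all core labelings) and check that no class member violates a cut
check_cut_validity <- function(g, kind, problem = "sce") {
  ev <- frac_point(g, 0.5)
  cv <- stats::setNames(rep(0.5, n_vertices(g)), g$vertices)
  cuts <- separate_cuts(g, ev, cv, kind = kind, problem = problem,
                        min_violation = -10, max_cuts = 20L)
  prs <- cpedit:::all_pairs(g$vertices)
  np <- nrow(prs)
  vs <- g$vertices
  for (mask in 0:(2^np - 1L)) {
    keep <- bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0L
    h <- cp_graph(vs, prs[keep, , drop = FALSE])
    ehm <- adjacency_matrix(h) * 1
    if (kind %in% c("C4", "P5")) {
      if (!is_split_cluster(h)$member) next
      for (ct in cuts) {
        expect_gte(cpedit:::cut_lhs(ct, ehm), ct$rhs - 1e-9)
      }
    } else if (kind == "W4") {
      if (!is_monopolar_bruteforce(h)$monopolar) next
      for (ct in cuts) {
        expect_gte(cpedit:::cut_lhs(ct, ehm), ct$rhs - 1e-9)
      }
    } else {
      for (cmask in 0:(2^length(vs) - 1L)) {
        core <- vs[bitwAnd(cmask, 2^(seq_along(vs) - 1L)) > 0L]
        part <- list(core = core, periphery = setdiff(vs, core))
        ok <- if (problem == "sce") {
          check_annotated_split_cluster(h, part)$ok
        } else {
          check_annotated_monopolar(h, part)$ok
        }
        if (!ok) next
        cvh <- stats::setNames(as.numeric(vs %in% core), vs)
        for (ct in cuts) {
          expect_gte(cpedit:::cut_lhs(ct, ehm, cvh), ct$rhs - 1e-9)
        }
      }
    }
  }
}

test_that("cuts never exclude a feasible integral solution", {
  check_cut_validity(path_graph(3L), "P3", "sce")
  check_cut_validity(path_graph(3L), "P3", "me")
  check_cut_validity(cycle_graph(4L), "C4")
  check_cut_validity(path_graph(5L), "P5")
  check_cut_validity(w4_graph(), "W4")
})
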