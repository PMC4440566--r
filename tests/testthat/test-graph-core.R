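test_that("edge-list parsing collapses duplicates and rejects self-loops", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb", "b\tc"), f)
  g <- read_edge_list(f)
  expect_equal(n_vertices(g), 3L)
  expect_equal(n_edges(g), 2L)

  writeLines(c("a\tb", "b\ta"), f)
  expect_equal(n_edges(read_edge_list(f)), 1L)

  writeLines("a\ta", f)
  expect_error(read_edge_list(f), "self-loop")

  writeLines(c("# comment", "a\tb", "", "z"), f)
  g <- read_edge_list(f)
  expect_true("z" %in% g$vertices)
  expect_equal(n_edges(g), 1L)

  writeLines(c("a pp b", "b pp c", "d"), f)
  gs <- read_edge_list(f, dialect = "sif")
  expect_equal(n_edges(gs), 2L)
  expect_true("d" %in% gs$vertices)
  writeLines("a pp", f)
  expect_error(read_edge_list(f, dialect = "sif"), "line 1")
})

test_that("edge lists round-trip through write_edge_list", {
  for (seed in 1:5) {
    g <- er_graph(8, 0.3, seed = seed)
    f <- withr::local_tempfile()
    write_edge_list(g, f)
    expect_true(graph_equal(read_edge_list(f), g))
  }
})

test_that("connected components are maximal, sorted, deterministic", {
  tri2 <- cp_graph(edges = cbind(c("a", "a", "b", "x", "x", "y"),
                                 c("b", "c", "c", "y", "z", "z")))
  expect_equal(connected_components(tri2),
               list(c("a", "b", "c"), c("x", "y", "z")))
  expect_equal(connected_components(cp_graph(c("b", "a"))),
               list("a", "b"))
  expect_equal(lengths(connected_components(path_graph(5L))), 5L)
})

test_that("induced subgraphs keep exactly the inner edges", {
  c5 <- cycle_graph(5L)
  sub <- induced_subgraph(c5, c("a", "b", "c"))
  expect_equal(n_edges(sub), 2L)   # a path
  expect_equal(n_vertices(induced_subgraph(c5, character())), 0L)
  k3 <- induced_subgraph(complete_graph(4L), c("a", "b", "c"))
  expect_equal(n_edges(k3), 3L)
  expect_error(induced_subgraph(c5, "nope"), "unknown")
})

test_that("apply_edits follows edge-set arithmetic and validates", {
  c5 <- cycle_graph(5L)
  e <- edit_set(deletions = rbind(c("a", "b"), c("b", "c")), g = c5)
  h <- apply_edits(c5, e)
  expect_equal(n_edges(h), 3L)
  comps <- connected_components(h)
  expect_equal(sort(lengths(comps)), c(1L, 4L))  # P4 plus isolated b

  expect_true(graph_equal(apply_edits(c5, edit_set()), c5))

  g22 <- two_k2_graph()
  h2 <- apply_edits(g22, edit_set(insertions = rbind(c("b", "c")), g = g22))
  expect_equal(cpedit:::canonical_key(h2), cpedit:::canonical_key(path_graph(4L)))

  expect_error(edit_set(insertions = rbind(c("a", "b")), g = c5), "already present")
  expect_error(edit_set(deletions = rbind(c("a", "c")), g = c5), "absent")
  expect_error(edit_set(insertions = rbind(c("a", "c")),
                        deletions = rbind(c("a", "c"))), "overlap")
})

test_that("applying an edit set twice restores the graph", {
  for (seed in 1:10) {
    g <- er_graph(7, 0.4, seed = seed)
    prs <- cpedit:::all_pairs(g$vertices)
    idx <- withr::with_seed(seed, sample.int(nrow(prs), 4L))
    h <- cpedit:::toggle_pairs(g, prs[idx, , drop = FALSE])
    e <- cpedit:::edit_diff(g, h)
    expect_true(graph_equal(apply_edits(h, edit_set(e$deletions, e$insertions, g = h)), g))
    expect_true(graph_equal(apply_edits(apply_edits(g, e),
                                        edit_set(e$deletions, e$insertions,
                                                 g = apply_edits(g, e))), g))
  }
})

test_that("component count shifts weakly under single-edge edits", {
  for (seed in 1:10) {
    g <- er_graph(8, 0.25, seed = 100 + seed)
    k0 <- length(connected_components(g))
    prs <- cpedit:::all_pairs(g$vertices)
    pk <- paste(prs[, 1], prs[, 2], sep = "\t")
    absent <- prs[!(pk %in% cpedit:::edge_keys(g)), , drop = FALSE]
    if (nrow(absent)) {
      h <- apply_edits(g, edit_set(insertions = absent[1L, , drop = FALSE], g = g))
      expect_lte(length(connected_components(h)), k0)
    }
    if (n_edges(g)) {
      h <- apply_edits(g, edit_set(deletions = g$edges[1L, , drop = FALSE], g = g))
      expect_gte(length(connected_components(h)), k0)
    }
  }
})

test_that("component diameters match hand-computed values", {
  expect_equal(component_diameter(complete_graph(3L), c("a", "b", "c")), 1L)
  expect_equal(component_diameter(path_graph(5L), letters[1:5]), 4L)
  nt <- necktie_graph()
  expect_equal(component_diameter(nt, nt$vertices), 3L)
  expect_error(component_diameter(two_k2_graph(), c("a", "b", "c", "d")),
               "not connected")
})
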