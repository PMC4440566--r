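test_that("SCE solvers reproduce hand-checked objectives", {
  cfg <- fast_cfg()
  c5 <- cycle_graph(5L)
  expect_equal(solve_sce_forbidden(c5, cfg)$objective, 2L)
  expect_equal(solve_sce_partition(c5, cfg)$objective, 2L)

  # a split graph is already a split cluster graph
  split_g <- apply_edits(necktie_graph(),
                         edit_set(deletions = rbind(c("c", "d")),
                                  g = necktie_graph()))
  r <- solve_sce_forbidden(split_g, cfg)
  expect_equal(r$objective, 0L)
  expect_equal(edit_size(r$edits), 0L)

  expect_equal(solve_sce_forbidden(path_graph(5L), cfg)$objective, 1L)
  expect_equal(solve_sce_partition(path_graph(5L), cfg)$objective, 1L)

  star <- cp_graph(edges = cbind("hub", c("l1", "l2", "l3")))
  rs <- solve_sce_partition(star, cfg)
  expect_equal(rs$objective, 0L)
  expect_equal(rs$partition$clusters[[1L]]$core, "hub")
  expect_setequal(rs$partition$clusters[[1L]]$periphery, c("l1", "l2", "l3"))
})

test_that("ME and CE solvers reproduce hand-checked objectives", {
  cfg <- fast_cfg()
  rme <- solve_me_partition(path_graph(5L), cfg)
  expect_equal(rme$objective, 0L)  # P5 is monopolar, e.g. periphery {b, d}
  expect_true(check_annotated_monopolar(
    path_graph(5L),
    list(core = setdiff(letters[1:5], rme$partition$shared_periphery),
         periphery = rme$partition$shared_periphery))$ok)

  expect_gte(solve_me_partition(w4_graph(), cfg)$objective, 1L)
  cl <- cp_graph(edges = rbind(t(utils::combn(c("a", "b", "c"), 2L)),
                               c("x", "y")))
  expect_equal(solve_me_partition(cl, cfg)$objective, 0L)

  expect_equal(solve_ce(path_graph(3L), cfg)$objective, 1L)
  expect_equal(solve_ce(cl, cfg)$objective, 0L)
  expect_equal(solve_ce(path_graph(5L), cfg)$objective, 2L)
})

test_that("solutions are feasible for their class and edits match objectives", {
  for (seed in 1:10) {
    g <- er_graph(7, 0.35, seed = 40 + seed)
    cfg <- fast_cfg(seed)
    for (res in list(solve_sce_forbidden(g, cfg), solve_sce_partition(g, cfg))) {
      expect_true(is_split_cluster(res$graph)$member)
      expect_equal(res$objective, edit_size(res$edits))
      expect_true(graph_equal(apply_edits(g, res$edits), res$graph))
    }
    rme <- solve_me_partition(g, cfg)
    expect_true(check_annotated_monopolar(
      rme$graph,
      list(core = setdiff(g$vertices, rme$partition$shared_periphery),
           periphery = rme$partition$shared_periphery))$ok)
    rce <- solve_ce(g, cfg)
    expect_true(is_cluster_graph(rce$graph)$member)
    expect_true(all(vapply(connected_components(rce$graph), function(comp) {
      n_edges(induced_subgraph(rce$graph, comp)) == choose(length(comp), 2L)
    }, logical(1L))))
  }
})

test_that("degree-one periphery fixing is applied and preserves the optimum", {
  star <- cp_graph(edges = cbind("hub", c("l1", "l2", "l3")))
  m <- ilp_model(star, "sce_partition")
  m <- fix_variables_obs1(star, m)
  fixed <- m$fixed
  names(fixed) <- m$var_names
  for (l in c("l1", "l2", "l3")) {
    expect_equal(fixed[[paste0("c:", l)]], 0L)
  }
  expect_equal(fixed[["e:l1\tl2"]], 0L)
  expect_equal(fixed[["e:l1\tl3"]], 0L)
  expect_equal(fixed[["e:l2\tl3"]], 0L)
  expect_true(is.na(fixed[["e:hub\tl1"]]))

  k2 <- cp_graph(edges = rbind(c("u", "v")))
  m2 <- fix_variables_obs1(k2, ilp_model(k2, "sce_partition"))
  expect_true(all(is.na(m2$fixed)))
  tri <- complete_graph(3L)
  m3 <- fix_variables_obs1(tri, ilp_model(tri, "sce_partition"))
  expect_true(all(is.na(m3$fixed)))

  for (seed in 1:8) {
    base <- er_graph(5, 0.5, seed = 60 + seed)
    g <- cp_graph(c(base$vertices, "x1", "x2"),
                  rbind(base$edges, c(base$vertices[1L], "x1"),
                        c(base$vertices[2L], "x2")))
    with_fix <- solve_sce_partition(g, fast_cfg(seed))
    without <- solve_sce_partition(g, solve_cfg(seed = seed,
                                                fix_degree_one = FALSE,
                                                warm_steps = 2000L,
                                                warm_restarts = 4L))
    expect_equal(with_fix$objective, without$objective)
  }
})

test_that("row generation settings do not change the optimum", {
  for (seed in 1:6) {
    g <- er_graph(7, 0.4, seed = 80 + seed)
    base <- solve_sce_partition(g, fast_cfg(seed))$objective
    no_cuts <- solve_cfg(cuts = FALSE, seed = seed, warm_steps = 2000L,
                         warm_restarts = 4L)
    expect_equal(solve_sce_forbidden(g, no_cuts)$objective, base)
    with_cuts <- solve_cfg(cuts = TRUE, seed = seed, warm_steps = 2000L,
                           warm_restarts = 4L)
    expect_equal(solve_sce_forbidden(g, with_cuts)$objective, base)
    cold <- solve_cfg(warm_start = FALSE, seed = seed)
    expect_equal(solve_sce_partition(g, cold)$objective, base)
  }
})
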