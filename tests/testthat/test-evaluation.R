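test_that("complex filtering applies its three steps in order", {
  g <- cp_graph(paste0("p", 1:6))
  cx <- list(
    half_out = c("p1", "p2", "q1", "q2", "q3"),      # 2/5 inside: dropped
    restricted = c("p1", "p2", "p3", "q1"),          # 3/4 inside: kept, cut
    too_small = c("p1", "p2"),                       # 2/2 inside but < 3
    full = c("p4", "p5", "p6"))
  out <- filter_complexes(cx, g)
  expect_named(out, c("restricted", "full"))
  expect_setequal(out$restricted, c("p1", "p2", "p3"))
})

test_that("nontrivial clusters need three vertices and two core vertices", {
  p <- core_periphery_partition(list(
    list(core = c("a", "b"), periphery = "c"),        # nontrivial
    list(core = "d", periphery = paste0("x", 1:5)),   # single core vertex
    list(core = "e", periphery = character())),       # singleton
    mode = "per_cluster")
  nt <- nontrivial_clusters(p)
  expect_length(nt, 1L)
  expect_setequal(nt[[1L]]$core, c("a", "b"))
})

test_that("detection thresholds and percentages follow the 50% rule", {
  p <- core_periphery_partition(list(
    list(core = paste0("p", 1:3), periphery = c("p4", "z1"))),
    mode = "per_cluster")
  cx <- list(cplx = paste0("p", 1:4))
  rep1 <- detect_complexes(p, cx)
  expect_true(rep1$per_complex$detected)
  expect_equal(rep1$per_complex$core_pct, 100)
  expect_equal(rep1$per_complex$comp_pct, 100)
  expect_equal(rep1$per_complex$extra_pct, 50)
  expect_equal(rep1$summary$D, 1L)

  # core passes at exactly 50% but complex coverage fails at 25%
  p2 <- core_periphery_partition(list(
    list(core = c("p1", "w1"), periphery = character())),
    mode = "per_cluster")
  rep2 <- detect_complexes(p2, list(cplx = c("p1", "q2", "q3", "q4")))
  expect_false(rep2$per_complex$detected)
  expect_equal(rep2$summary$D, 0L)

  # empty periphery: extra percentage defined as zero
  p3 <- core_periphery_partition(list(
    list(core = paste0("p", 1:3), periphery = character())),
    mode = "per_cluster")
  rep3 <- detect_complexes(p3, list(cplx = paste0("p", 1:3)))
  expect_equal(rep3$per_complex$extra_pct, 0)
})

test_that("a complex is counted once and the best detecting cluster reported", {
  p <- core_periphery_partition(list(
    list(core = c("p1", "p2"), periphery = "p3"),
    list(core = c("p4", "p5"), periphery = c("p1", "p2", "p3"))),
    mode = "shared", shared_periphery = character())
  cx <- list(cplx = paste0("p", 1:5))
  rep <- detect_complexes(p, cx)
  expect_equal(rep$summary$D, 1L)
  expect_equal(rep$per_complex$cluster, 2L)  # covers 5/5 vs 3/5
})

test_that("enlarging a detecting cluster's periphery cannot un-detect", {
  for (seed in 1:10) {
    vs <- paste0("p", 1:8)
    comp <- withr::with_seed(seed, sample(vs, 4L))
    core <- comp[1:2]
    peri <- setdiff(vs, core)[1:2]
    p1 <- core_periphery_partition(list(list(core = core, periphery = peri)),
                                   mode = "per_cluster")
    d1 <- detect_complexes(p1, list(cx = comp))$per_complex$detected
    p2 <- core_periphery_partition(list(list(
      core = core, periphery = union(peri, setdiff(vs, c(core, peri))))),
      mode = "per_cluster")
    d2 <- detect_complexes(p2, list(cx = comp))$per_complex$detected
    if (d1) expect_true(d2)
  }
})

test_that("zero-noise planted cores are detected perfectly", {
  pl <- planted_instance(c(4L, 3L), c(2L, 2L), "disjoint", seed = 9L)
  cx <- lapply(pl$truth$clusters, `[[`, "core")
  names(cx) <- paste0("complex", seq_along(cx))
  rep <- detect_complexes(pl$truth, cx)
  expect_equal(rep$summary$D, 2L)
  expect_true(all(rep$per_complex$core_pct == 100))
  expect_true(all(rep$per_complex$comp_pct == 100))
})

test_that("partition statistics aggregate over nontrivial clusters", {
  p <- core_periphery_partition(list(
    list(core = c("a", "b", "c"), periphery = c("d", "e"))),
    mode = "per_cluster")
  e <- edit_set(insertions = rbind(c("a", "b"), c("c", "d")),
                deletions = rbind(c("x", "y"), c("y", "z")))
  st <- partition_stats(p, e)
  expect_equal(st$k, 4L)
  expect_equal(st$K, 1L)
  expect_equal(st$c_bar, 3)
  expect_equal(st$p_bar, 2)

  singles <- core_periphery_partition(
    lapply(letters[1:4], function(v) list(core = v)), mode = "per_cluster")
  expect_equal(partition_stats(singles)$K, 0L)

  p2 <- core_periphery_partition(list(
    list(core = c("a", "b"), periphery = "x"),
    list(core = c("c", "d", "e", "f"), periphery = "y")),
    mode = "per_cluster")
  expect_equal(partition_stats(p2)$c_bar, 3)
})

test_that("shared-mode peripheries are the core neighborhoods in the graph", {
  pm <- planted_instance(c(3L, 3L), 3L, "shared", seed = 6L)
  al <- cpedit:::adjacency_list(pm$graph)
  for (cl in pm$truth$clusters) {
    nb <- setdiff(sort(unique(unlist(al[cl$core]))), cl$core)
    expect_equal(cl$periphery, nb)
  }
})

test_that("partitions write and re-read through the TSV interface", {
  pl <- planted_instance(c(3L, 2L), c(1L, 2L), "disjoint", seed = 2L)
  f <- withr::local_tempfile()
  write_partition(pl$truth, f)
  df <- utils::read.table(f, sep = "\t",
                          col.names = c("vertex", "cluster", "role"))
  expect_setequal(df$vertex, pl$graph$vertices)
  expect_setequal(unique(df$role), c("core", "periphery"))
})
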