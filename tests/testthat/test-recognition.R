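test_that("split recognition returns valid verdicts and witnesses", {
  r <- is_split(cycle_graph(4L))
  expect_false(r$split)
  expect_equal(r$certificate$kind, "C4")
  expect_true(check_certificate(cycle_graph(4L), r$certificate))

  expect_true(is_split(cp_graph("a"))$split)

  r <- is_split(path_graph(4L))
  expect_true(r$split)
  expect_setequal(r$partition$core, c("b", "c"))
  expect_setequal(r$partition$periphery, c("a", "d"))

  r <- is_split(two_k2_graph())
  expect_equal(r$certificate$kind, "2K2")
  r <- is_split(cycle_graph(5L))
  expect_equal(r$certificate$kind, "C5")
  expect_true(check_certificate(cycle_graph(5L), r$certificate))
})

test_that("splittance matches brute-force editing on the worked examples", {
  expect_equal(splittance(rep(2L, 5L)), 2L)         # C5
  expect_equal(split_edit_bruteforce(cycle_graph(5L)), 2L)
  expect_equal(splittance(rep(1L, 4L)), 1L)         # 2K2
  expect_equal(split_edit_bruteforce(two_k2_graph()), 1L)
  expect_equal(splittance(rep(2L, 3L)), 0L)         # K3
  expect_error(splittance(c(3L, 1L)), "graphical")
  expect_error(splittance(c(1L)), "graphical")
  expect_equal(splittance(integer()), 0L)
})

test_that("split cluster recognition produces the advertised certificates", {
  r <- is_split_cluster(path_graph(5L))
  expect_false(r$member)
  expect_equal(r$certificate$kind, "P5")
  expect_true(check_certificate(path_graph(5L), r$certificate))

  tri2 <- cp_graph(edges = cbind(c("a", "a", "b", "x", "x", "y"),
                                 c("b", "c", "c", "y", "z", "z")))
  expect_true(is_split_cluster(tri2)$member)

  for (gmk in list(bowtie_graph, necktie_graph)) {
    g <- gmk()
    r <- is_split_cluster(g)
    expect_false(r$member)
    expect_true(check_certificate(g, r$certificate))
  }
  expect_equal(is_split_cluster(bowtie_graph())$certificate$kind, "bowtie")
  expect_equal(is_split_cluster(necktie_graph())$certificate$kind, "necktie")
})

test_that("2K2 localization follows the shortest-path case analysis", {
  p5 <- path_graph(5L)
  loc <- localize_2K2(p5, c("a", "b"), c("d", "e"))
  expect_setequal(loc$pair1, c("a", "b"))
  expect_setequal(loc$pair2, c("d", "e"))
  expect_equal(loc$v, "c")

  p6 <- path_graph(6L)
  loc <- localize_2K2(p6, c("a", "b"), c("e", "f"))
  a <- adjacency_matrix(p6)
  expect_true(any(a[loc$v, loc$pair1]) && any(a[loc$v, loc$pair2]))
  expect_true(check_certificate(
    p6, certificate("2K2", c(loc$pair1, loc$pair2))))

  nt <- necktie_graph()
  loc <- localize_2K2(nt, c("a", "b"), c("c", "d"))
  expect_equal(loc$v, "v")

  expect_error(localize_2K2(p5, c("a", "b"), c("c", "d")), "2K2")
  g2 <- two_k2_graph()
  expect_error(localize_2K2(g2, c("a", "b"), c("c", "d")), "components")
})

test_that("annotated split cluster check reports edge and P3 violations", {
  k2 <- cp_graph(edges = rbind(c("u", "v")))
  r <- check_annotated_split_cluster(k2, list(core = character(),
                                              periphery = c("u", "v")))
  expect_false(r$ok)
  expect_equal(r$violation$type, "edge")

  p3 <- path_graph(3L)
  r <- check_annotated_split_cluster(p3, list(core = c("a", "c"),
                                              periphery = "b"))
  expect_false(r$ok)
  expect_equal(r$violation$type, "P3")

  empty <- cp_graph(c("x", "y"))
  expect_true(check_annotated_split_cluster(
    empty, list(core = "x", periphery = "y"))$ok)
  expect_error(check_annotated_split_cluster(
    p3, list(core = "a", periphery = "b")), "partition")
})

test_that("annotated monopolar check only forbids all-core P3s", {
  p3 <- path_graph(3L)
  expect_true(check_annotated_monopolar(p3, list(core = c("a", "c"),
                                                 periphery = "b"))$ok)
  r <- check_annotated_monopolar(p3, list(core = c("a", "b", "c"),
                                          periphery = character()))
  expect_false(r$ok)
  expect_equal(r$violation$type, "P3")
  k4 <- complete_graph(4L)
  expect_true(check_annotated_monopolar(
    k4, list(core = k4$vertices, periphery = character()))$ok)
})

test_that("monopolar model accepts whatever the split cluster model accepts", {
  for (seed in 1:25) {
    g <- er_graph(6, 0.4, seed = 300 + seed)
    core <- withr::with_seed(seed, sample(g$vertices, 3L))
    part <- list(core = core, periphery = setdiff(g$vertices, core))
    if (check_annotated_split_cluster(g, part)$ok) {
      expect_true(check_annotated_monopolar(g, part)$ok)
    }
  }
})

test_that("brute-force monopolar recognition matches known facts", {
  expect_false(is_monopolar_bruteforce(w4_graph())$monopolar)
  r <- is_monopolar_bruteforce(cycle_graph(5L))
  expect_true(r$monopolar)
  expect_true(check_annotated_monopolar(cycle_graph(5L), r$partition)$ok)
  expect_true(is_monopolar_bruteforce(complete_graph(3L))$monopolar)
  expect_error(is_monopolar_bruteforce(er_graph(25, 0.2, 1)), "25")
})

test_that("recognizer certificates always verify on random graphs", {
  for (seed in 1:40) {
    g <- er_graph(8, 0.35, seed = 700 + seed)
    r <- is_split_cluster(g)
    if (!r$member) {
      expect_true(check_certificate(g, r$certificate))
      expect_true(r$certificate$kind %in% c("C4", "C5", "P5", "necktie", "bowtie"))
    } else {
      for (comp in connected_components(g)) {
        expect_lte(component_diameter(g, comp), 3L)
      }
    }
    rs <- is_split(g)
    expect_equal(rs$split, splittance(cpedit:::vertex_degrees(g)) == 0L)
    if (!rs$split) expect_true(check_certificate(g, rs$certificate))
  }
})
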