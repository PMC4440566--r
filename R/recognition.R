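# Certificate-producing recognition of split graphs, split cluster graphs,
# and (brute-force) monopolar graphs.
#
# A split graph partitions into a clique and an independent set; it is
# exactly a (2K2, C4, C5)-free graph, and membership is decided by the
# degree sequence alone (splittance = 0). A split cluster graph has split
# components and is exactly (C4, C5, P5, necktie, bowtie)-free: a 2K2 found
# inside one component can always be relocated next to a common witness
# vertex, and the five vertices then induce a P5 (no extra edge), a necktie
# (one extra edge), or a bowtie (both).

# positional edge patterns for every certificate kind (indices into the
# vertex tuple); the induced subgraph on the tuple must match exactly
.cert_patterns <- list(
  P3      = list(n = 3L, edges = rbind(c(1, 2), c(2, 3))),
  `2K2`   = list(n = 4L, edges = rbind(c(1, 2), c(3, 4))),
  C4      = list(n = 4L, edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))),
  C5      = list(n = 5L, edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5))),
  P5      = list(n = 5L, edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5))),
  # triangle 1-2-3 with the path 3-4-5 hanging off vertex 3
  necktie = list(n = 5L, edges = rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(4, 5))),
  # two triangles 1-2-3 and 3-4-5 sharing vertex 3
  bowtie  = list(n = 5L, edges = rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 5))),
  # 4-cycle 1-2-3-4 plus hub 5 adjacent to all cycle vertices
  W4      = list(n = 5L, edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4),
                                       c(1, 5), c(2, 5), c(3, 5), c(4, 5)))
)

#' Typed forbidden-subgraph certificate
#'
#' A witness that a graph is outside a class: a kind (one of `2K2`, `C4`,
#' `C5`, `P5`, `necktie`, `bowtie`, `P3`, `W4`) and an ordered vertex tuple
#' whose induced subgraph is isomorphic to that kind. Tuple positions follow
#' fixed conventions (cycle order for cycles, path order for paths, triangle
#' vertices then tail for the necktie, hub in the middle for the bowtie, hub
#' last for the wheel).
#'
#' @param kind Certificate kind.
#' @param vertices Ordered character tuple of distinct labels.
#' @return Object of class `cp_certificate`.
#' @export
certificate <- function(kind, vertices) {
  kind <- match.arg(kind, names(.cert_patterns))
  vertices <- as.character(vertices)
  pat <- .cert_patterns[[kind]]
  if (length(vertices) != pat$n || anyDuplicated(vertices)) {
    stop("certificate '", kind, "' needs ", pat$n, " distinct vertices")
  }
  structure(list(kind = kind, vertices = vertices), class = "cp_certificate")
}

#' @export
print.cp_certificate <- function(x, ...) {
  cat("<certificate> ", x$kind, ": ", paste(x$vertices, collapse = "-"), "\n",
      sep = "")
  invisible(x)
}

#' Verify a certificate against a graph
#'
#' Checks that the induced subgraph on the certificate's vertex tuple has
#' exactly the edge pattern of its kind (positionally).
#'
#' @param g A `cp_graph`.
#' @param cert A [certificate()].
#' @return Logical.
#' @export
check_certificate <- function(g, cert) {
  stopifnot(inherits(cert, "cp_certificate"))
  vs <- cert$vertices
  if (!all(vs %in% g$vertices)) return(FALSE)
  pat <- .cert_patterns[[cert$kind]]
  want <- paste(pmin(vs[pat$edges[, 1L]], vs[pat$edges[, 2L]]),
                pmax(vs[pat$edges[, 1L]], vs[pat$edges[, 2L]]), sep = "\t")
  sub <- induced_subgraph(g, vs)
  setequal(edge_keys(sub), want) && n_edges(sub) == nrow(pat$edges)
}

#' Splittance of a degree sequence
#'
#' The minimum number of edge edits turning any graph with the given degree
#' sequence into a split graph. With degrees sorted descending and `k` the
#' largest index with `d[k] >= k - 1`, the value is
#' `(k(k-1) - sum(d[1:k]) + sum(d[-(1:k)])) / 2`: the missing pairs inside
#' the top-`k` clique candidate plus the edges left among the rest. A graph
#' is split exactly when its splittance is zero.
#'
#' @param degrees Nonnegative integer vector; must be a graphical degree
#'   sequence (checked by the Erdos-Gallai conditions).
#' @return Nonnegative integer.
#' @examples
#' splittance(rep(2, 5))  # C5 needs 2 edits
#' @export
splittance <- function(degrees) {
  degrees <- as.integer(degrees)
  if (length(degrees) == 0L) return(0L)
  if (any(degrees < 0L)) stop("degrees must be nonnegative")
  if (!is_graphical_sequence(degrees)) {
    stop("`degrees` is not a graphical degree sequence")
  }
  d <- sort(degrees, decreasing = TRUE)
  n <- length(d)
  k <- max(which(d >= seq_len(n) - 1L))
  as.integer((k * (k - 1L) - sum(d[seq_len(k)]) + sum(d[-seq_len(k)])) / 2L)
}

# Erdos-Gallai: even sum and the k-th partial-sum conditions
is_graphical_sequence <- function(degrees) {
  d <- sort(as.integer(degrees), decreasing = TRUE)
  n <- length(d)
  if (n == 0L) return(TRUE)
  if (d[1L] > n - 1L) return(FALSE)
  if (sum(d) %% 2L != 0L) return(FALSE)
  for (k in seq_len(n)) {
    rhs <- k * (k - 1L) + sum(pmin(d[-seq_len(k)], k))
    if (sum(d[seq_len(k)]) > rhs) return(FALSE)
  }
  TRUE
}

# split partition of a split graph: with degrees sorted descending and k as
# in the splittance formula, the top k vertices form a clique and the rest
# an independent set (ties broken lexicographically); checked before return
split_partition <- function(g) {
  n <- n_vertices(g)
  if (n == 0L) return(list(core = character(), periphery = character()))
  deg <- vertex_degrees(g)
  o <- order(-deg, names(deg), method = "radix")
  d <- deg[o]
  k <- max(which(d >= seq_len(n) - 1L))
  core <- sort(names(d)[seq_len(k)])
  periphery <- sort(setdiff(g$vertices, core))
  a <- adjacency_matrix(g)
  stopifnot(all(a[core, core][upper.tri(diag(length(core)))]),
            !any(a[periphery, periphery]))
  list(core = core, periphery = periphery)
}

#' Recognize split graphs with a certificate
#'
#' Decides membership via the degree sequence (splittance zero); on
#' failure, extracts an induced 2K2, C4 or C5, and on success a witnessing
#' clique / independent-set partition.
#'
#' @param g A `cp_graph`.
#' @return List with `split` (logical), `certificate` (a [certificate()] of
#'   kind `2K2`, `C4` or `C5`, or `NULL`), and `partition` (list with
#'   `core`, `periphery`, or `NULL`).
#' @export
is_split <- function(g) {
  if (splittance(vertex_degrees(g)) == 0L) {
    return(list(split = TRUE, certificate = NULL,
                partition = split_partition(g)))
  }
  cert <- find_split_obstruction(g)
  stopifnot(!is.null(cert), check_certificate(g, cert))
  list(split = FALSE, certificate = cert, partition = NULL)
}

# locate an induced 2K2, C4 or C5 in a non-split graph; deterministic scan
# over edge pairs in lexicographic order, then C5 via induced P4 completion
find_split_obstruction <- function(g) {
  em <- g$edges
  m <- nrow(em)
  a <- adjacency_matrix(g)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      u1 <- em[i, 1L]; v1 <- em[i, 2L]
      for (j in seq(i + 1L, m)) {
        u2 <- em[j, 1L]; v2 <- em[j, 2L]
        if (u2 %in% c(u1, v1) || v2 %in% c(u1, v1)) next
        cross <- c(a[u1, u2], a[u1, v2], a[v1, u2], a[v1, v2])
        if (!any(cross)) {
          return(certificate("2K2", c(u1, v1, u2, v2)))
        }
        # an induced C4 is two disjoint edges joined by exactly the two
        # cross edges of a perfect matching between them
        if (sum(cross) == 2L) {
          if (a[u1, u2] && a[v1, v2]) {
            return(certificate("C4", c(v1, u1, u2, v2)))
          }
          if (a[u1, v2] && a[v1, u2]) {
            return(certificate("C4", c(u1, v1, u2, v2)))
          }
        }
      }
    }
  }
  # no 2K2 and no C4: any remaining obstruction is a C5; close an induced P4
  al <- adjacency_list(g)
  for (i in seq_len(m)) {
    b <- em[i, 1L]; cc <- em[i, 2L]
    for (ord in list(c(b, cc), c(cc, b))) {
      x <- ord[1L]; y <- ord[2L]
      as_ <- setdiff(al[[x]], c(al[[y]], y))
      ds_ <- setdiff(al[[y]], c(al[[x]], x))
      for (aa in as_) {
        for (dd in ds_) {
          if (aa == dd || a[aa, dd]) next
          # induced P4 aa-x-y-dd; find e adjacent to both ends only
          for (ee in intersect(al[[aa]], al[[dd]])) {
            if (ee %in% c(x, y)) next
            if (!a[ee, x] && !a[ee, y]) {
              return(certificate("C5", c(ee, aa, x, y, dd)))
            }
          }
        }
      }
    }
  }
  NULL
}

#' Relocate a 2K2 next to a common witness vertex
#'
#' Given an induced 2K2 inside one connected component, returns a (possibly
#' different) induced 2K2 together with a vertex outside it adjacent to at
#' least one endpoint of each of its edges, following the shortest-path case
#' analysis (path length 2, 3, or longer between the two edges).
#'
#' @param g A `cp_graph`.
#' @param pair1,pair2 Character vectors of length 2, the two edges.
#' @return List with `pair1`, `pair2` (each length-2 character) and `v`.
#' @export
localize_2K2 <- function(g, pair1, pair2) {
  pair1 <- as.character(pair1); pair2 <- as.character(pair2)
  cert <- certificate("2K2", c(pair1, pair2))
  if (!check_certificate(g, cert)) {
    stop("`pair1`, `pair2` do not induce a 2K2 in `g`")
  }
  ig <- as_igraph(g)
  dmat <- igraph::distances(ig, v = pair1, to = pair2)
  if (any(is.infinite(dmat))) {
    stop("the two edges lie in different connected components")
  }
  # pick the closest endpoint pair; relabel so the path runs x1 ... y1
  best <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
  x1 <- pair1[best[1L]]; x2 <- setdiff(pair1, x1)
  y1 <- pair2[best[2L]]; y2 <- setdiff(pair2, y1)
  sp <- igraph::shortest_paths(ig, from = x1, to = y1)$vpath[[1L]]
  p <- igraph::vertex_attr(ig, "name")[as.integer(sp)]
  k <- length(p)
  stopifnot(k > 2L)
  res <- if (k == 3L) {
    list(pair1 = c(x1, x2), pair2 = c(y1, y2), v = p[2L])
  } else if (k == 4L) {
    list(pair1 = c(x2, x1), pair2 = c(p[3L], p[4L]), v = p[2L])
  } else {
    list(pair1 = c(p[1L], p[2L]), pair2 = c(p[4L], p[5L]), v = p[3L])
  }
  stopifnot(check_certificate(g, certificate("2K2", c(res$pair1, res$pair2))))
  a <- adjacency_matrix(g)
  stopifnot(any(a[res$v, res$pair1]), any(a[res$v, res$pair2]))
  res
}

# classify the five vertices around a localized 2K2: with v adjacent to one
# endpoint of each edge, the number of additional v-edges decides P5 (0),
# necktie (1), or bowtie (2)
classify_localized <- function(g, loc) {
  a <- adjacency_matrix(g)
  p1 <- loc$pair1; p2 <- loc$pair2; v <- loc$v
  adj1 <- a[v, p1]; adj2 <- a[v, p2]
  n1 <- sum(adj1); n2 <- sum(adj2)
  stopifnot(n1 >= 1L, n2 >= 1L)
  if (n1 == 1L && n2 == 1L) {
    aa <- p1[adj1]; bb <- p1[!adj1]
    cc <- p2[adj2]; dd <- p2[!adj2]
    cert <- certificate("P5", c(bb, aa, v, cc, dd))
  } else if (n1 == 2L && n2 == 2L) {
    cert <- certificate("bowtie", c(p1, v, p2))
  } else if (n1 == 2L) {
    cc <- p2[adj2]; dd <- p2[!adj2]
    cert <- certificate("necktie", c(p1, v, cc, dd))
  } else {
    aa <- p1[adj1]; bb <- p1[!adj1]
    cert <- certificate("necktie", c(p2, v, aa, bb))
  }
  stopifnot(check_certificate(g, cert))
  cert
}

#' Recognize split cluster graphs with a certificate
#'
#' A graph is a split cluster graph when every connected component is a
#' split graph. Each component is tested via its degree sequence; a C4 or
#' C5 obstruction is returned directly, while a 2K2 is relocated with
#' [localize_2K2()] and classified as P5, necktie, or bowtie.
#'
#' @param g A `cp_graph`.
#' @return List with `member` (logical) and `certificate` (kind `C4`, `C5`,
#'   `P5`, `necktie` or `bowtie`, or `NULL`).
#' @export
is_split_cluster <- function(g) {
  for (comp in connected_components(g)) {
    sub <- induced_subgraph(g, comp)
    res <- is_split(sub)
    if (res$split) next
    cert <- res$certificate
    if (cert$kind %in% c("C4", "C5")) {
      return(list(member = FALSE, certificate = cert))
    }
    loc <- localize_2K2(sub, cert$vertices[1:2], cert$vertices[3:4])
    out <- classify_localized(sub, loc)
    stopifnot(check_certificate(g, out))
    return(list(member = FALSE, certificate = out))
  }
  list(member = TRUE, certificate = NULL)
}

# per-component core/periphery of a split cluster graph; errors otherwise
split_cluster_partition <- function(g) {
  lapply(connected_components(g), function(comp) {
    sp <- is_split(induced_subgraph(g, comp))
    stopifnot(sp$split)
    sp$partition
  })
}

#' Check an annotated core/periphery partition for the split cluster model
#'
#' Given a vertex bipartition into cores `C` and periphery `I`, the graph is
#' a split cluster graph with that annotation iff there is no edge inside
#' `I` and no induced P3 with both endpoints in `C`.
#'
#' @param g A `cp_graph`.
#' @param partition List with character components `core` and `periphery`
#'   partitioning the vertices of `g`.
#' @return List with `ok` (logical) and `violation` (`NULL`, or a list with
#'   `type = "edge"` and the offending pair, or `type = "P3"` and a
#'   [certificate()]).
#' @export
check_annotated_split_cluster <- function(g, partition) {
  check_annotated(g, partition, endpoints_only = TRUE)
}

#' Check an annotated partition for the monopolar model
#'
#' The graph is monopolar with periphery `I` and cores `C` iff `I` is an
#' independent set and the subgraph induced by `C` has no induced P3 at all.
#'
#' @inheritParams check_annotated_split_cluster
#' @return As [check_annotated_split_cluster()].
#' @export
check_annotated_monopolar <- function(g, partition) {
  check_annotated(g, partition, endpoints_only = FALSE)
}

# endpoints_only = TRUE: forbid P3 with both *endpoints* in C (split cluster);
# FALSE: forbid P3 entirely inside C (monopolar)
check_annotated <- function(g, partition, endpoints_only) {
  C <- as.character(partition$core)
  I <- as.character(partition$periphery)
  if (!setequal(c(C, I), g$vertices) || length(intersect(C, I)) > 0L ||
      anyDuplicated(c(C, I))) {
    stop("`partition` must split the vertex set into disjoint core and periphery")
  }
  if (nrow(g$edges) > 0L) {
    both <- g$edges[, 1L] %in% I & g$edges[, 2L] %in% I
    if (any(both)) {
      e <- g$edges[which(both)[1L], ]
      return(list(ok = FALSE, violation = list(type = "edge", vertices = e)))
    }
  }
  a <- adjacency_matrix(g)
  al <- adjacency_list(g)
  mids <- if (endpoints_only) g$vertices else C
  for (m in mids) {
    nb <- if (endpoints_only) intersect(al[[m]], C) else intersect(al[[m]], C)
    if (length(nb) < 2L) next
    for (i in seq_len(length(nb) - 1L)) {
      for (j in seq(i + 1L, length(nb))) {
        if (!a[nb[i], nb[j]]) {
          cert <- certificate("P3", c(nb[i], m, nb[j]))
          return(list(ok = FALSE, violation = list(type = "P3", certificate = cert)))
        }
      }
    }
  }
  list(ok = TRUE, violation = NULL)
}

#' Monopolar recognition by exhaustive two-coloring
#'
#' Monopolar recognition is NP-hard in general; this routine searches all
#' core/periphery bipartitions with early pruning and is intended for small
#' graphs (oracle use). Vertices are processed per connected component in
#' lexicographic order.
#'
#' @param g A `cp_graph`.
#' @param max_n Size guard; graphs with more vertices are rejected.
#' @return List with `monopolar` (logical) and `partition` (list with
#'   `core`, `periphery`, or `NULL`).
#' @export
is_monopolar_bruteforce <- function(g, max_n = 20L) {
  n <- n_vertices(g)
  if (n > max_n) {
    stop("graph has ", n, " > ", max_n, " vertices; use the heuristic or ",
         "exact editing solver instead")
  }
  if (n == 0L) {
    return(list(monopolar = TRUE,
                partition = list(core = character(), periphery = character())))
  }
  a <- adjacency_matrix(g)
  vs <- g$vertices
  state <- integer(n)  # 0 unassigned, 1 core, 2 periphery
  ok_core <- function(i) {
    # adding vertex i to C must not complete a P3 inside C
    Cn <- which(state == 1L & a[i, ])     # core neighbors of i
    Co <- which(state == 1L & !a[i, ])    # core non-neighbors
    Co <- Co[Co != i]
    # i as middle or endpoint: a core neighbor u with a core vertex w such
    # that u-w adjacent pattern breaks transitivity
    for (u in Cn) {
      # i middle: two core neighbors of i nonadjacent
      for (w in Cn) if (w > u && !a[u, w]) return(FALSE)
      # i endpoint: u middle, w other endpoint in C nonadjacent to i
      for (w in Co) if (a[u, w]) return(FALSE)
    }
    TRUE
  }
  rec <- function(i) {
    if (i > n) {
      return(list(core = vs[state == 1L], periphery = vs[state == 2L]))
    }
    state[i] <<- 1L
    if (ok_core(i)) {
      r <- rec(i + 1L)
      if (!is.null(r)) return(r)
    }
    state[i] <<- 2L
    if (!any(state == 2L & a[i, ])) {  # periphery stays independent
      r <- rec(i + 1L)
      if (!is.null(r)) return(r)
    }
    state[i] <<- 0L
    NULL
  }
  res <- rec(1L)
  if (is.null(res)) {
    list(monopolar = FALSE, partition = NULL)
  } else {
    chk <- check_annotated_monopolar(g, res)
    stopifnot(chk$ok)
    list(monopolar = TRUE, partition = res)
  }
}
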