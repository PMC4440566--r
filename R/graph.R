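#' Construct an undirected simple graph with string vertex labels
#'
#' The basic container used throughout the package. Edges are unordered
#' pairs of distinct labels; duplicate and reversed duplicate edges collapse
#' to one. Isolated vertices are first-class.
#'
#' @param vertices Character vector of vertex labels (may be empty).
#' @param edges Two-column character matrix (or coercible data frame) of
#'   endpoints, or `NULL` for an edgeless graph. Endpoint labels not listed
#'   in `vertices` are added.
#' @return An object of class `cp_graph` with components `vertices`
#'   (sorted character vector) and `edges` (two-column character matrix in
#'   canonical order: each row sorted, rows lexicographic).
#' @examples
#' g <- cp_graph(edges = cbind(c("a", "b"), c("b", "c")))
#' n_vertices(g)
#' @export
cp_graph <- function(vertices = character(), edges = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) {
    vertices <- unique(vertices)
  }
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("`edges` must have two columns")
    storage.mode(em) <- "character"
    if (any(em[, 1L] == em[, 2L])) {
      bad <- which(em[, 1L] == em[, 2L])[1L]
      stop("self-loop on vertex '", em[bad, 1L], "' is not allowed")
    }
    em <- canonical_edges(em)
  }
  vertices <- sort(unique(c(vertices, as.vector(em))))
  structure(list(vertices = vertices, edges = em), class = "cp_graph")
}

# sort endpoints within rows, drop duplicates, order rows lexicographically
canonical_edges <- function(em) {
  u <- pmin(em[, 1L], em[, 2L])
  v <- pmax(em[, 1L], em[, 2L])
  k <- paste(u, v, sep = "\t")
  keep <- !duplicated(k)
  u <- u[keep]; v <- v[keep]
  o <- order(u, v, method = "radix")
  cbind(u[o], v[o], deparse.level = 0L)
}

pair_key <- function(u, v) {
  paste(pmin(u, v), pmax(u, v), sep = "\t")
}

#' @export
print.cp_graph <- function(x, ...) {
  cat("<cp_graph> ", n_vertices(x), " vertices, ", n_edges(x), " edges\n",
      sep = "")
  invisible(x)
}

#' Number of vertices / edges
#' @param g A `cp_graph`.
#' @return Integer count.
#' @export
n_vertices <- function(g) length(g$vertices)

#' @rdname n_vertices
#' @export
n_edges <- function(g) nrow(g$edges)

edge_keys <- function(g) {
  if (nrow(g$edges) == 0L) character() else paste(g$edges[, 1L], g$edges[, 2L], sep = "\t")
}

has_edge <- function(g, u, v) {
  pair_key(u, v) %in% edge_keys(g)
}

#' Logical adjacency matrix with vertex labels as dimnames
#' @param g A `cp_graph`.
#' @return Symmetric logical matrix.
#' @export
adjacency_matrix <- function(g) {
  n <- n_vertices(g)
  a <- matrix(FALSE, n, n, dimnames = list(g$vertices, g$vertices))
  if (nrow(g$edges) > 0L) {
    a[g$edges] <- TRUE
    a[g$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  a
}

# named list of neighbor character vectors
adjacency_list <- function(g) {
  al <- rep(list(character()), n_vertices(g))
  names(al) <- g$vertices
  if (nrow(g$edges) > 0L) {
    grp <- split(c(g$edges[, 2L], g$edges[, 1L]),
                 factor(c(g$edges[, 1L], g$edges[, 2L]), levels = g$vertices))
    al[names(grp)] <- lapply(grp, sort)
  }
  al
}

vertex_degrees <- function(g) {
  d <- stats::setNames(integer(n_vertices(g)), g$vertices)
  if (nrow(g$edges) > 0L) {
    tab <- table(factor(as.vector(g$edges), levels = g$vertices))
    d[] <- as.integer(tab)
  }
  d
}

#' Convert to and from igraph
#' @param g A `cp_graph`.
#' @return `as_igraph()` returns an [igraph::graph]; `from_igraph()` a
#'   `cp_graph` (vertex `name` attributes are used as labels).
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = 0, directed = FALSE)
  ig <- igraph::add_vertices(ig, n_vertices(g), name = g$vertices)
  if (nrow(g$edges) > 0L) ig <- igraph::add_edges(ig, t(g$edges))
  ig
}

#' @rdname as_igraph
#' @param ig An igraph object.
#' @export
from_igraph <- function(ig) {
  nm <- igraph::vertex_attr(ig, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(ig)))
  el <- igraph::as_edgelist(ig, names = FALSE)
  cp_graph(nm, cbind(nm[el[, 1L]], nm[el[, 2L]]))
}

#' Test two graphs for equality (same vertex set, same edge set)
#' @param g1,g2 `cp_graph` objects.
#' @return Logical.
#' @export
graph_equal <- function(g1, g2) {
  identical(g1$vertices, g2$vertices) && identical(g1$edges, g2$edges)
}

# all unordered pairs over a sorted label vector, lexicographic, 2-col matrix
all_pairs <- function(vertices) {
  n <- length(vertices)
  if (n < 2L) return(matrix(character(), ncol = 2L))
  idx <- utils::combn(n, 2L)
  cbind(vertices[idx[1L, ]], vertices[idx[2L, ]], deparse.level = 0L)
}

#' Connected components
#'
#' @param g A `cp_graph`.
#' @return List of character vectors (sorted within), one per maximal
#'   connected vertex set, ordered lexicographically by smallest member.
#' @examples
#' connected_components(cp_graph(c("a", "b")))
#' @export
connected_components <- function(g) {
  n <- n_vertices(g)
  if (n == 0L) return(list())
  comp <- igraph::components(as_igraph(g))$membership
  comps <- unname(split(g$vertices, comp[g$vertices]))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, character(1L), 1L))]
}

#' Induced subgraph
#'
#' @param g A `cp_graph`.
#' @param s Character vector of vertex labels, a subset of `g$vertices`.
#' @return The `cp_graph` on `s` with exactly the edges of `g` inside `s`.
#' @export
induced_subgraph <- function(g, s) {
  s <- as.character(s)
  unknown <- setdiff(s, g$vertices)
  if (length(unknown) > 0L) {
    stop("unknown vertex label(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(g$edges) == 0L) return(cp_graph(s))
  keep <- g$edges[, 1L] %in% s & g$edges[, 2L] %in% s
  cp_graph(s, g$edges[keep, , drop = FALSE])
}

#' Diameter of a connected component
#'
#' @param g A `cp_graph`.
#' @param comp Character vector of vertices forming a connected set in `g`.
#' @return Maximum shortest-path length between vertices of `comp`
#'   (0 for a single vertex).
#' @export
component_diameter <- function(g, comp) {
  sub <- induced_subgraph(g, comp)
  if (n_vertices(sub) <= 1L) return(0L)
  d <- igraph::distances(as_igraph(sub))
  if (any(is.infinite(d))) stop("`comp` is not connected in `g`")
  as.integer(max(d))
}

#' Edit sets: edge insertions and deletions
#'
#' An edit set records, relative to a host graph, which vertex pairs are
#' inserted and which edges are deleted; its size is the editing objective k.
#'
#' @param insertions,deletions Two-column character matrices of unordered
#'   pairs (or `NULL`).
#' @param g Optional host `cp_graph`; when given, the invariants
#'   (insertions disjoint from E, deletions a subset of E) are checked.
#' @return Object of class `cp_edit_set` with components `insertions`,
#'   `deletions` (canonical two-column matrices).
#' @export
edit_set <- function(insertions = NULL, deletions = NULL, g = NULL) {
  norm <- function(m) {
    if (is.null(m) || NROW(m) == 0L) return(matrix(character(), ncol = 2L))
    m <- as.matrix(m)
    storage.mode(m) <- "character"
    if (any(m[, 1L] == m[, 2L])) stop("edit set contains a self-loop pair")
    canonical_edges(m)
  }
  ins <- norm(insertions)
  del <- norm(deletions)
  ki <- paste(ins[, 1L], ins[, 2L], sep = "\t")
  kd <- paste(del[, 1L], del[, 2L], sep = "\t")
  if (length(intersect(ki, kd)) > 0L) {
    stop("insertions and deletions overlap")
  }
  if (!is.null(g)) {
    ek <- edge_keys(g)
    if (any(ki %in% ek)) stop("insertion of an edge already present")
    if (!all(kd %in% ek)) stop("deletion of an absent edge")
    vs <- g$vertices
    lab <- unique(c(as.vector(ins), as.vector(del)))
    if (!all(lab %in% vs)) stop("edit set mentions unknown vertex labels")
  }
  structure(list(insertions = ins, deletions = del), class = "cp_edit_set")
}

#' @export
print.cp_edit_set <- function(x, ...) {
  cat("<cp_edit_set> ", nrow(x$insertions), " insertions, ",
      nrow(x$deletions), " deletions (k = ", edit_size(x), ")\n", sep = "")
  invisible(x)
}

#' Size of an edit set (the parameter k)
#' @param e A `cp_edit_set`.
#' @return Integer.
#' @export
edit_size <- function(e) nrow(e$insertions) + nrow(e$deletions)

#' Apply an edit set to a graph
#'
#' Returns a new graph with the insertions added and the deletions removed.
#' Applying the same edit set twice restores the original graph.
#'
#' @param g A `cp_graph`.
#' @param e A `cp_edit_set` valid for `g`.
#' @return The edited `cp_graph` (same vertex set).
#' @export
apply_edits <- function(g, e) {
  stopifnot(inherits(e, "cp_edit_set"))
  e <- edit_set(e$insertions, e$deletions, g = g)  # validate against g
  ek <- edge_keys(g)
  kd <- paste(e$deletions[, 1L], e$deletions[, 2L], sep = "\t")
  keep <- !(ek %in% kd)
  cp_graph(g$vertices, rbind(g$edges[keep, , drop = FALSE], e$insertions))
}

# toggle a set of pairs (insert if absent, delete if present); internal
toggle_pairs <- function(g, pairs) {
  if (NROW(pairs) == 0L) return(g)
  pairs <- canonical_edges(as.matrix(pairs))
  pk <- paste(pairs[, 1L], pairs[, 2L], sep = "\t")
  stopifnot(!anyDuplicated(pk))
  ek <- edge_keys(g)
  del <- pairs[pk %in% ek, , drop = FALSE]
  ins <- pairs[!(pk %in% ek), , drop = FALSE]
  apply_edits(g, edit_set(ins, del, g = g))
}

# edit set transforming g into h (same vertex set); internal
edit_diff <- function(g, h) {
  stopifnot(identical(g$vertices, h$vertices))
  ekg <- edge_keys(g); ekh <- edge_keys(h)
  edit_set(h$edges[!(ekh %in% ekg), , drop = FALSE],
           g$edges[!(ekg %in% ekh), , drop = FALSE], g = g)
}
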