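#' Read a graph from an edge-list or SIF file
#'
#' The `tsv` dialect expects one edge per line as two whitespace/tab
#' separated labels; a line with a single field declares an isolated
#' vertex. The `sif` dialect expects `A relation B` triples and ignores the
#' relation. Lines starting with `#` and blank lines are skipped. Duplicate
#' and reversed duplicate edges collapse to one; self-loops are rejected.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"sif"`.
#' @return A [cp_graph()].
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  verts <- character()
  from <- character()
  to <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (dialect == "sif") {
      if (length(f) == 1L) {
        verts <- c(verts, f[1L])
        next
      }
      if (length(f) < 3L) {
        stop("parse error at line ", i, ": SIF line needs 'A relation B'")
      }
      u <- f[1L]; v <- f[3L]
    } else {
      if (length(f) == 1L) {
        verts <- c(verts, f[1L])
        next
      }
      u <- f[1L]; v <- f[2L]
    }
    if (u == v) stop("self-loop at line ", i, ": '", u, "'")
    from <- c(from, u); to <- c(to, v)
  }
  cp_graph(verts, cbind(from, to))
}

#' Write a graph as a two-column tab-separated edge list
#'
#' Isolated vertices are written as single-field lines, so that
#' `read_edge_list()` round-trips the graph exactly.
#'
#' @param g A `cp_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  lines <- character()
  if (nrow(g$edges) > 0L) {
    lines <- paste(g$edges[, 1L], g$edges[, 2L], sep = "\t")
  }
  iso <- setdiff(g$vertices, unique(as.vector(g$edges)))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a gold-standard complex file
#'
#' One complex per line: tab-separated fields, the first being the complex
#' name and the rest its member labels.
#'
#' @param path Path to the file.
#' @return Named list of character vectors (members per complex).
#' @export
read_complexes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  cx <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 2L) stop("complex line ", i, " has no members")
    cx[[f[1L]]] <- unique(f[-1L])
  }
  cx
}

#' Write a core-periphery partition as a three-column TSV
#'
#' Columns: vertex, cluster id, role (`core` or `periphery`). In shared
#' mode the shared periphery is written with cluster id 0.
#'
#' @param p A [core_periphery_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(p, path) {
  rows <- character()
  for (i in seq_along(p$clusters)) {
    cl <- p$clusters[[i]]
    rows <- c(rows,
              if (length(cl$core)) paste(cl$core, i, "core", sep = "\t"),
              if (p$mode == "per_cluster" && length(cl$periphery)) {
                paste(cl$periphery, i, "periphery", sep = "\t")
              })
  }
  if (p$mode == "shared" && length(p$shared_periphery)) {
    rows <- c(rows, paste(p$shared_periphery, 0L, "periphery", sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
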