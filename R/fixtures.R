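#' Bundled example digraphs
#'
#' Three small 9-vertex digraphs used throughout the worked examples and
#' regression tests, reconstructed from their degree-class counts:
#' \describe{
#'   \item{g2}{the directed path `v1 -> v2 -> ... -> v9`; both degree
#'     polynomials equal `8x + 1`.}
#'   \item{g3}{the out-star: one center with edges to 8 leaves;
#'     `P_out = x^8 + 8`, `P_in = 8x + 1`.}
#'   \item{g4}{seven sources pointing at a hub plus one hub-to-sink edge;
#'     `P_out = 8x + 1`, `P_in = x^7 + x + 7`. Non-isomorphic to g2 despite
#'     sharing its out-polynomial (a degenerate pair).}
#' }
#'
#' @return named list of simple directed `igraph` objects.
#' @export
example_graphs <- function() {
  path9 <- digraph(cbind(paste0("v", 1:8), paste0("v", 2:9)))
  star9 <- digraph(cbind("c", paste0("l", 1:8)))
  hub <- digraph(rbind(cbind(paste0("s", 1:7), "h"), c("h", "t")))
  list(g2 = path9, g3 = star9, g4 = hub)
}

#' Bundled example degree polynomials
#'
#' Polynomial-level fixtures for the worked examples whose full edge sets
#' are not reconstructible from degree data alone, plus the polynomials of
#' the reconstructible graphs in [example_graphs()]. Coefficients are given
#' lowest degree first. `hier23_out` is the out-polynomial of a 23-vertex
#' hierarchical digraph used in the dominance walkthrough
#' (`x^8 + x^7 + 5x^5 + 10x + 6`); `hier23_out_alt` is a variant of the
#' same example with the degree-5 term moved to degree 2 (consistent with
#' an edge count of 35 rather than 50) — the dominance demos use the
#' degree-5 form.
#'
#' @return named list of `degree_polynomial` objects.
#' @export
example_polynomials <- function() {
  list(
    g1_out = degree_polynomial(c(3, 0, 0, 1, 2, 0, 1, 2), "out"),
    g1_in = degree_polynomial(c(2, 0, 1, 1, 1, 2, 2), "in"),
    g2_out = degree_polynomial(c(1, 8), "out"),
    g2_in = degree_polynomial(c(1, 8), "in"),
    g3_out = degree_polynomial(c(8, 0, 0, 0, 0, 0, 0, 0, 1), "out"),
    g3_in = degree_polynomial(c(1, 8), "in"),
    g4_out = degree_polynomial(c(1, 8), "out"),
    g4_in = degree_polynomial(c(7, 1, 0, 0, 0, 0, 0, 1), "in"),
    g5_out = degree_polynomial(c(4, 2, 1, 1), "out"),
    g6_out = degree_polynomial(c(6, 3, 2, 2), "out"),
    hier23_out = degree_polynomial(c(6, 10, 0, 0, 0, 5, 0, 1, 1), "out"),
    hier23_out_alt = degree_polynomial(c(6, 10, 5, 0, 0, 0, 0, 1, 1), "out")
  )
}

#' Read a degree polynomial from JSON
#'
#' The serialization is an object with a `direction` tag and a
#' `coefficients` array of non-negative integers, lowest degree first.
#'
#' @param path JSON file path.
#' @return a `degree_polynomial`.
#' @export
read_polynomial_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$coefficients)) stop("no 'coefficients' field in ", path)
  dir <- if (is.null(obj$direction)) "raw" else obj$direction
  degree_polynomial(obj$coefficients, dir)
}

#' Write a degree polynomial to JSON
#'
#' @param p a `degree_polynomial`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_polynomial_json <- function(p, path) {
  stopifnot(inherits(p, "degree_polynomial"))
  jsonlite::write_json(list(direction = p$direction,
                            coefficients = p$coefficients),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Write all bundled fixtures to a directory
#'
#' Edge-list files for the reconstructible example graphs and one JSON file
#' per example polynomial.
#'
#' @param dir destination directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_example_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  gs <- example_graphs()
  for (nm in names(gs)) {
    path <- file.path(dir, paste0(nm, ".edges"))
    write_digraph(gs[[nm]], path)
    paths <- c(paths, path)
  }
  ps <- example_polynomials()
  for (nm in names(ps)) {
    path <- file.path(dir, paste0(nm, ".json"))
    write_polynomial_json(ps[[nm]], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
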