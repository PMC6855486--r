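#' Construct a simple directed graph
#'
#' Digraphs in this package are simple: no self-loops, no multi-edges. They
#' are stored as directed \pkg{igraph} objects; any function accepting a
#' digraph validates these invariants first.
#'
#' @param edges two-column character matrix or data.frame of (from, to)
#'   pairs, or a length-2n character vector taken row-wise.
#' @param vertices optional character vector of vertex names; must contain
#'   every edge endpoint. Isolated vertices are kept.
#' @return a directed `igraph` object.
#' @examples
#' g <- digraph(rbind(c("a", "b"), c("b", "c")))
#' igraph::vcount(g)
#' @export
digraph <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges) || (is.character(edges) && length(edges) == 0) ||
      (is.matrix(edges) && nrow(edges) == 0)) {
    em <- matrix(character(0), ncol = 2)
  } else if (is.data.frame(edges)) {
    em <- as.matrix(edges[, 1:2])
  } else if (is.matrix(edges)) {
    em <- edges[, 1:2, drop = FALSE]
  } else {
    em <- matrix(as.character(edges), ncol = 2, byrow = TRUE)
  }
  storage.mode(em) <- "character"
  loops <- em[, 1] == em[, 2]
  if (any(loops)) {
    stop("self-loop not allowed: (", em[which(loops)[1], 1], ", ",
         em[which(loops)[1], 2], ")")
  }
  key <- paste(em[, 1], em[, 2], sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate edge not allowed: (", em[d, 1], ", ", em[d, 2], ")")
  }
  verts <- unique(c(vertices, as.vector(t(em))))
  if (length(verts) < 1) stop("a digraph needs at least one vertex")
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (nrow(em) > 0) g <- igraph::add_edges(g, as.vector(t(em)))
  g
}

#' Validate a simple digraph
#'
#' @param graph object to check.
#' @return the graph, invisibly; errors on violation.
#' @export
validate_digraph <- function(graph) {
  if (!igraph::is_igraph(graph)) stop("not an igraph object")
  if (!igraph::is_directed(graph)) stop("graph must be directed")
  if (igraph::vcount(graph) < 1) stop("a digraph needs at least one vertex")
  if (igraph::any_loop(graph)) stop("graph must not contain self-loops")
  if (igraph::any_multiple(graph)) stop("graph must not contain multi-edges")
  invisible(graph)
}

#' Out- or in-degree of one vertex
#'
#' @param graph a simple digraph.
#' @param vertex vertex name (or index).
#' @param direction `"out"` or `"in"`.
#' @return non-negative integer degree.
#' @examples
#' g <- digraph(rbind(c("a", "b"), c("a", "c")))
#' degree_of(g, "a", "out")
#' @export
degree_of <- function(graph, vertex, direction = c("out", "in")) {
  validate_digraph(graph)
  direction <- match.arg(direction)
  if (is.character(vertex) && !(vertex %in% igraph::V(graph)$name)) {
    stop("unknown vertex: ", vertex)
  }
  as.integer(igraph::degree(graph, v = vertex, mode = direction))
}

#' Degree-class counts of a digraph
#'
#' Counts the vertices of each out- (or in-) degree: entry `j + 1` of the
#' returned vector is the number of vertices with degree exactly `j`,
#' for `j = 0, ..., kmax`. These counts are exactly the coefficients of the
#' degree polynomial.
#'
#' @inheritParams degree_of
#' @return object of class `degree_class_counts`: an integer vector named
#'   `"0", "1", ...` with attribute `direction`.
#' @examples
#' g <- digraph(rbind(c("a", "b"), c("b", "c")))
#' degree_class_counts(g, "out")
#' @export
degree_class_counts <- function(graph, direction = c("out", "in")) {
  validate_digraph(graph)
  direction <- match.arg(direction)
  deg <- igraph::degree(graph, mode = direction)
  counts <- tabulate(deg + 1L, nbins = max(deg) + 1L)
  counts <- as.integer(counts)
  names(counts) <- as.character(seq_along(counts) - 1L)
  structure(counts, direction = direction, class = "degree_class_counts")
}

#' @export
print.degree_class_counts <- function(x, ...) {
  cat("Degree-class counts (", attr(x, "direction"), "-degree)\n", sep = "")
  print(unclass(structure(as.integer(x), names = names(x))))
  invisible(x)
}

#' Weak connectivity
#'
#' TRUE iff the underlying undirected graph is connected.
#'
#' @param graph a simple digraph.
#' @return logical scalar.
#' @export
is_weakly_connected <- function(graph) {
  validate_digraph(graph)
  igraph::is_connected(graph, mode = "weak")
}

#' Reverse every edge
#'
#' @param graph a simple digraph.
#' @return the digraph with all edges reversed.
#' @export
reverse_digraph <- function(graph) {
  validate_digraph(graph)
  igraph::reverse_edges(graph)
}

#' Read a digraph from a file
#'
#' The edge-list dialect is one whitespace-separated `u v` pair per line;
#' blank lines and lines starting with `#` are ignored. GraphML files are
#' read through \pkg{igraph}.
#'
#' @param path file path.
#' @param format `"edge_list"` or `"graphml"`.
#' @return a simple directed `igraph` object.
#' @export
read_digraph <- function(path, format = c("edge_list", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (!igraph::is_directed(g)) stop("GraphML file is not a directed graph")
    return(validate_digraph(g))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  edges <- matrix(character(0), ncol = 2)
  for (i in which(keep)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2) {
      stop("malformed edge-list line ", i, " in ", path, ": '", lines[i], "'")
    }
    if (tok[1] == tok[2]) {
      stop("self-loop in ", path, " at line ", i, ": (", tok[1], ", ",
           tok[2], ")")
    }
    edges <- rbind(edges, tok)
  }
  key <- paste(edges[, 1], edges[, 2])
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate edge in ", path, ": (", edges[d, 1], ", ", edges[d, 2], ")")
  }
  digraph(edges)
}

#' Write a digraph to a file
#'
#' @param graph a simple digraph.
#' @param path destination path.
#' @param format `"edge_list"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_digraph <- function(graph, path, format = c("edge_list", "graphml")) {
  validate_digraph(graph)
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph, names = TRUE)
    writeLines(paste(el[, 1], el[, 2]), path)
  }
  invisible(path)
}
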