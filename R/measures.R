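#' Edge density of a digraph
#'
#' `|E| / (|V|^2 - |V|)`: the filled fraction of possible directed edges
#' (index I7).
#'
#' @param graph a simple digraph with at least 2 vertices.
#' @return numeric in \[0, 1\].
#' @export
edge_density_digraph <- function(graph) {
  validate_digraph(graph)
  n <- igraph::vcount(graph)
  if (n < 2) stop("edge density undefined for |V| < 2")
  igraph::ecount(graph) / (n^2 - n)
}

#' Complexity indices of a digraph
#'
#' Builds both degree polynomials, selects alpha for each under the given
#' policy, solves for the two zeros and derives the indices:
#' `I1 = delta_out`, `I2 = delta_in`, `I3 = (I1 + I2)/2`,
#' `I4 = (sqrt(I1) + sqrt(I2))/2`, `I5 = |ln I1| + |ln I2|`, and the edge
#' density `I7`. The numbering deliberately skips I6.
#'
#' @param graph a simple digraph with at least 2 vertices and at least one
#'   edge.
#' @inheritParams select_alpha
#' @return object of class `measure_vector`: a list with fields
#'   `delta_out`, `delta_in`, `alpha_out`, `alpha_in`, `I1`...`I5`, `I7`,
#'   `n_vertices`, `n_edges`.
#' @examples
#' path9 <- digraph(cbind(paste0("v", 1:8), paste0("v", 2:9)))
#' compute_measures(path9)$I1   # 0.125
#' @export
compute_measures <- function(graph, policy = c("min_integer", "midpoint")) {
  validate_digraph(graph)
  policy <- match.arg(policy)
  if (igraph::ecount(graph) < 1) {
    stop("measures undefined: no admissible alpha (graph has no edges)")
  }
  if (igraph::vcount(graph) < 2) stop("measures need at least 2 vertices")
  mv <- measures_from_polynomials(build_polynomial(graph, "out"),
                                  build_polynomial(graph, "in"),
                                  policy = policy)
  # handshake guarantees the polynomial-derived counts match the graph
  stopifnot(mv$n_vertices == igraph::vcount(graph))
  mv
}

#' Complexity indices from a pair of degree polynomials
#'
#' Same computation as [compute_measures()] for graphs known only through
#' their printed polynomials (vertex and edge counts are recovered from the
#' coefficient sums: `|V| = sum(a_j)`, `|E| = sum(j * a_j)`, identical for
#' the two directions of any digraph).
#'
#' @param p_out,p_in out- and in-degree polynomials of one digraph.
#' @inheritParams select_alpha
#' @return a `measure_vector`; see [compute_measures()].
#' @export
measures_from_polynomials <- function(p_out, p_in,
                                      policy = c("min_integer", "midpoint")) {
  policy <- match.arg(policy)
  stopifnot(inherits(p_out, "degree_polynomial"),
            inherits(p_in, "degree_polynomial"))
  n_out <- sum(p_out$coefficients)
  m_out <- sum((seq_along(p_out$coefficients) - 1L) * p_out$coefficients)
  n_in <- sum(p_in$coefficients)
  m_in <- sum((seq_along(p_in$coefficients) - 1L) * p_in$coefficients)
  if (n_out != n_in || m_out != m_in) {
    stop("polynomials are inconsistent: vertex/edge totals differ ",
         "(", n_out, "/", m_out, " vs ", n_in, "/", m_in, ")")
  }
  sel_out <- select_alpha(p_out, policy)
  sel_in <- select_alpha(p_in, policy)
  d_out <- unique_positive_zero(p_out, sel_out$alpha)$delta
  d_in <- unique_positive_zero(p_in, sel_in$alpha)$delta
  structure(list(
    delta_out = d_out, delta_in = d_in,
    alpha_out = sel_out$alpha, alpha_in = sel_in$alpha,
    I1 = d_out, I2 = d_in,
    I3 = (d_out + d_in) / 2,
    I4 = (sqrt(d_out) + sqrt(d_in)) / 2,
    I5 = abs(log(d_out)) + abs(log(d_in)),
    I7 = m_out / (n_out^2 - n_out),
    n_vertices = as.integer(n_out), n_edges = as.integer(m_out)
  ), class = "measure_vector")
}

#' @export
print.measure_vector <- function(x, ...) {
  cat("Digraph complexity measures (|V| = ", x$n_vertices, ", |E| = ",
      x$n_edges, ")\n", sep = "")
  cat("  alpha_out = ", x$alpha_out, ", alpha_in = ", x$alpha_in, "\n",
      sep = "")
  for (nm in c("I1", "I2", "I3", "I4", "I5", "I7")) {
    cat("  ", nm, " = ", formatC(x[[nm]], digits = 6, format = "f"), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.measure_vector <- function(x, ...) {
  data.frame(n_vertices = x$n_vertices, n_edges = x$n_edges,
             alpha_out = x$alpha_out, alpha_in = x$alpha_in,
             delta_out = x$delta_out, delta_in = x$delta_in,
             I1 = x$I1, I2 = x$I2, I3 = x$I3, I4 = x$I4, I5 = x$I5,
             I7 = x$I7)
}
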