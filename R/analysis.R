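#' Measure table for a list of digraphs
#'
#' One row per graph: vertex/edge counts, both alphas, both zeros, and the
#' indices I1-I5, I7. Per-graph failures (e.g. an edgeless graph) are
#' collected as warnings and reported in the `error` column, not fatal.
#'
#' @param graphs list of simple digraphs.
#' @inheritParams select_alpha
#' @param ids optional character vector of row identifiers; defaults to
#'   list names or `g1, g2, ...`.
#' @return data.frame with columns `graph_id`, `n_vertices`, `n_edges`,
#'   `alpha_out`, `alpha_in`, `delta_out`, `delta_in`, `I1`...`I5`, `I7`,
#'   `error`.
#' @export
measure_table <- function(graphs, policy = c("min_integer", "midpoint"),
                          ids = NULL) {
  policy <- match.arg(policy)
  if (is.null(ids)) {
    ids <- if (!is.null(names(graphs)) && all(nzchar(names(graphs)))) {
      names(graphs)
    } else {
      paste0("g", seq_along(graphs))
    }
  }
  empty <- data.frame(graph_id = character(0), n_vertices = integer(0),
                      n_edges = integer(0), alpha_out = numeric(0),
                      alpha_in = numeric(0), delta_out = numeric(0),
                      delta_in = numeric(0), I1 = numeric(0),
                      I2 = numeric(0), I3 = numeric(0), I4 = numeric(0),
                      I5 = numeric(0), I7 = numeric(0),
                      error = character(0))
  if (length(graphs) == 0) return(empty)
  rows <- lapply(seq_along(graphs), function(i) {
    res <- tryCatch(compute_measures(graphs[[i]], policy),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("graph ", ids[i], ": ", conditionMessage(res))
      data.frame(graph_id = ids[i], n_vertices = NA_integer_,
                 n_edges = NA_integer_, alpha_out = NA_real_,
                 alpha_in = NA_real_, delta_out = NA_real_,
                 delta_in = NA_real_, I1 = NA_real_, I2 = NA_real_,
                 I3 = NA_real_, I4 = NA_real_, I5 = NA_real_,
                 I7 = NA_real_, error = conditionMessage(res))
    } else {
      cbind(data.frame(graph_id = ids[i]), as.data.frame(res),
            data.frame(error = NA_character_))
    }
  })
  do.call(rbind, rows)
}

#' Spearman correlation matrix of the complexity indices
#'
#' Pairwise Spearman rank correlations (average ranks for ties) over the
#' index columns of a measure table. A constant column has no defined rank
#' correlation; its entries are `NA` and the column is named in the
#' `undefined` attribute rather than silently propagated.
#'
#' @param table a data.frame from [measure_table()] (rows with errors are
#'   dropped), or any data.frame containing the index columns.
#' @param columns index columns to correlate.
#' @return a symmetric matrix of class `correlation_matrix` with unit
#'   diagonal, attributes `n` (rows used) and `undefined` (constant
#'   columns).
#' @export
spearman_matrix <- function(table,
                            columns = c("I1", "I2", "I3", "I4", "I5", "I7")) {
  stopifnot(all(columns %in% names(table)))
  x <- table[stats::complete.cases(table[, columns]), columns, drop = FALSE]
  if (nrow(x) < 3) stop("need at least 3 complete rows")
  constant <- vapply(x, function(v) length(unique(v)) == 1L, logical(1))
  m <- suppressWarnings(stats::cor(x, method = "spearman"))
  m[constant, ] <- NA_real_
  m[, constant] <- NA_real_
  diag(m) <- 1
  structure(m, n = nrow(x), undefined = columns[constant],
            class = c("correlation_matrix", "matrix", "array"))
}

#' @export
print.correlation_matrix <- function(x, digits = 4, ...) {
  cat("Spearman correlation (n = ", attr(x, "n"), ")\n", sep = "")
  print(round(unclass(x), digits))
  und <- attr(x, "undefined")
  if (length(und)) {
    cat("undefined (constant columns):", paste(und, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Homogeneity records for a list of digraphs
#'
#' For each graph and each direction: the number of integer alpha
#' candidates `k`, the homogeneity score `h` of the candidate zero set, and
#' the zero range. Graphs whose admissible interval contains no integer get
#' `k = 1`, `h = 0` (single midpoint zero).
#'
#' @param graphs list of simple digraphs.
#' @param ids optional row identifiers.
#' @return data.frame with columns `graph_id`, `direction`, `k`, `h`,
#'   `min_delta`, `max_delta`.
#' @export
homogeneity_distribution <- function(graphs, ids = NULL) {
  if (is.null(ids)) {
    ids <- if (!is.null(names(graphs)) && all(nzchar(names(graphs)))) {
      names(graphs)
    } else {
      paste0("g", seq_along(graphs))
    }
  }
  rows <- list(data.frame(graph_id = character(0), direction = character(0),
                          k = integer(0), h = numeric(0),
                          min_delta = numeric(0), max_delta = numeric(0)))
  for (i in seq_along(graphs)) {
    for (dir in c("out", "in")) {
      p <- build_polynomial(graphs[[i]], dir)
      sel <- select_alpha(p, "min_integer")
      if (length(sel$candidates) == 0L) {
        d <- unique_positive_zero(p, sel$alpha)$delta
        rec <- data.frame(graph_id = ids[i], direction = dir, k = 1L,
                          h = 0, min_delta = d, max_delta = d)
      } else {
        zs <- zeros_over_candidates(p)
        rec <- data.frame(graph_id = ids[i], direction = dir,
                          k = length(zs$deltas),
                          h = homogeneity_score(zs),
                          min_delta = min(zs$deltas),
                          max_delta = max(zs$deltas))
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}

#' Correlation analysis of a freshly generated graph class
#'
#' Generates a pairwise non-isomorphic connected sample from the class,
#' computes the measure table under the minimum-integer alpha policy, and
#' returns the Spearman matrix together with the table.
#'
#' @inheritParams sample_class
#' @return list with `spec`, `table` and `correlation`.
#' @export
correlate_class <- function(spec, attempts_per_graph = 200L) {
  graphs <- sample_class(spec, attempts_per_graph)
  tab <- measure_table(graphs)
  list(spec = spec, table = tab, correlation = spearman_matrix(tab))
}
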