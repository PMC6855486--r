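#' Construct a degree polynomial
#'
#' A degree polynomial holds non-negative integer coefficients
#' `a_0, ..., a_k` (lowest degree first, `a_j` multiplies `x^j`). When built
#' from a digraph, `a_j` is the number of vertices with out- (or in-) degree
#' `j`, so the coefficient sum equals `|V|` and the degree-weighted sum
#' equals `|E|`. Coefficients are kept as exact integers; only root
#' iteration uses floating point.
#'
#' @param coefficients numeric vector of non-negative integers, `a_0` first.
#'   Trailing zero coefficients are trimmed so that `a_k > 0` (a constant
#'   zero polynomial is rejected).
#' @param direction `"out"`, `"in"`, or `"raw"` for polynomials not tied to
#'   a graph direction.
#' @return object of class `degree_polynomial`.
#' @examples
#' degree_polynomial(c(1, 8))   # 8x + 1
#' @export
degree_polynomial <- function(coefficients, direction = c("raw", "out", "in")) {
  direction <- match.arg(direction)
  if (length(coefficients) < 1) stop("coefficient vector is empty")
  if (any(!is.finite(coefficients)) || any(coefficients < 0) ||
      any(coefficients != round(coefficients))) {
    stop("coefficients must be non-negative integers")
  }
  coefficients <- as.integer(round(coefficients))
  k <- max(which(coefficients > 0L), 1L)
  coefficients <- coefficients[seq_len(k)]
  structure(list(coefficients = coefficients, direction = direction),
            class = "degree_polynomial")
}

#' Build the out- or in-degree polynomial of a digraph
#'
#' The coefficient of `x^j` is the number of vertices with degree `j` in the
#' chosen direction.
#'
#' @inheritParams degree_of
#' @return a `degree_polynomial` whose coefficients are the degree-class
#'   counts of `graph`.
#' @examples
#' path9 <- digraph(cbind(paste0("v", 1:8), paste0("v", 2:9)))
#' build_polynomial(path9, "out")   # 8x + 1
#' @export
build_polynomial <- function(graph, direction = c("out", "in")) {
  direction <- match.arg(direction)
  counts <- degree_class_counts(graph, direction)
  degree_polynomial(as.integer(counts), direction)
}

#' @export
print.degree_polynomial <- function(x, ...) {
  a <- x$coefficients
  j <- seq_along(a) - 1L
  keep <- a > 0L | j == 0L
  term <- ifelse(j == 0L, as.character(a),
                 paste0(ifelse(a == 1L, "", a),
                        ifelse(j == 1L, "x", paste0("x^", j))))
  cat("P_", x$direction, "(x) = ",
      paste(rev(term[keep]), collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Polynomial degree
#' @param p a `degree_polynomial`.
#' @return integer degree `k`.
#' @export
poly_degree <- function(p) length(p$coefficients) - 1L

#' Evaluate a degree polynomial
#'
#' Horner evaluation of `P(x) = a_k x^k + ... + a_1 x + a_0`; vectorised
#' over `x`.
#'
#' @param p a `degree_polynomial`.
#' @param x numeric vector of evaluation points.
#' @return numeric vector `P(x)`.
#' @export
evaluate_poly <- function(p, x) {
  a <- as.numeric(p$coefficients)
  res <- rep(a[length(a)], length(x))
  for (j in rev(seq_len(length(a) - 1L))) res <- res * x + a[j]
  res
}

#' Evaluate the alpha-shifted polynomial
#'
#' `P*(x) = alpha - P(x)`, the modified polynomial whose unique positive
#' zero is the complexity measure delta.
#'
#' @inheritParams evaluate_poly
#' @param alpha shift parameter.
#' @return numeric vector `alpha - P(x)`.
#' @export
evaluate_modified <- function(p, alpha, x) alpha - evaluate_poly(p, x)

#' Admissible range for the shift parameter alpha
#'
#' `alpha - P(x)` has its unique positive zero inside (0, 1) exactly when
#' `a_0 < alpha < sum(a_j)`. For graph-built polynomials the upper bound is
#' the vertex count.
#'
#' @param p a `degree_polynomial` with at least one positive coefficient of
#'   degree >= 1 (for a graph: at least one edge in that direction).
#' @return numeric `c(lower, upper)`, both exclusive.
#' @examples
#' alpha_bounds(degree_polynomial(c(3, 0, 0, 1, 2, 0, 1, 2)))  # (3, 9)
#' @export
alpha_bounds <- function(p) {
  stopifnot(inherits(p, "degree_polynomial"))
  a <- p$coefficients
  if (length(a) < 2L || all(a[-1L] == 0L)) {
    stop("no admissible alpha: polynomial is constant (graph has no edges ",
         "in this direction)")
  }
  c(lower = as.numeric(a[1L]), upper = as.numeric(sum(a)))
}

#' Select the shift parameter alpha
#'
#' The default policy picks the smallest integer strictly inside the
#' admissible interval; when the interval contains no integer the midpoint
#' is used and the policy is recorded as `"midpoint"`. An explicit value is
#' validated against the bounds.
#'
#' @param p a `degree_polynomial`.
#' @param policy `"min_integer"`, `"midpoint"`, or `"explicit"`.
#' @param value alpha value when `policy = "explicit"`.
#' @return object of class `alpha_selection` with fields `lower`, `upper`,
#'   `candidates` (sorted integers strictly inside the interval), `alpha`
#'   and `policy`.
#' @examples
#' select_alpha(degree_polynomial(c(1, 8)))          # candidates 2..8, alpha 2
#' select_alpha(degree_polynomial(c(8, 0, 0, 0, 0, 0, 0, 0, 1)))  # midpoint 8.5
#' @export
select_alpha <- function(p, policy = c("min_integer", "midpoint", "explicit"),
                         value = NULL) {
  policy <- match.arg(policy)
  b <- alpha_bounds(p)
  candidates <- alpha_candidates(b[1L], b[2L])
  if (policy == "explicit") {
    if (is.null(value)) stop("policy 'explicit' requires a value")
    if (value <= b[1L] || value >= b[2L]) {
      stop("alpha = ", value, " outside the admissible open interval (",
           b[1L], ", ", b[2L], ")")
    }
    alpha <- as.numeric(value)
  } else if (policy == "midpoint" || length(candidates) == 0L) {
    alpha <- unname(b[1L] + b[2L]) / 2
    policy <- "midpoint"
  } else {
    alpha <- as.numeric(candidates[1L])
  }
  structure(list(lower = unname(b[1L]), upper = unname(b[2L]),
                 candidates = candidates, alpha = alpha, policy = policy),
            class = "alpha_selection")
}

# integers strictly inside the open interval (lower, upper)
alpha_candidates <- function(lower, upper) {
  lo <- floor(lower) + 1L
  hi <- ceiling(upper) - 1L
  if (lo > hi) return(integer(0))
  out <- seq.int(lo, hi)
  out[out > lower & out < upper]
}

#' @export
print.alpha_selection <- function(x, ...) {
  cat("alpha in (", x$lower, ", ", x$upper, "), policy ", x$policy,
      ", chosen ", x$alpha, "\n", sep = "")
  if (length(x$candidates)) {
    cat("integer candidates: {", paste(x$candidates, collapse = ", "),
        "}\n", sep = "")
  }
  invisible(x)
}

#' Unique positive zero of the alpha-shifted polynomial
#'
#' For `a_0 < alpha < sum(a_j)` the coefficient sequence of
#' `P*(x) = alpha - P(x)` has exactly one sign change, so by Descartes' rule
#' `P*` has a unique positive zero, and `P*(0) > 0 > P*(1)` places it in
#' (0, 1). The zero is isolated by Brent's bracketed method on (0, 1)
#' (guaranteed sign change, derivative-free), bracket tolerance 1e-12,
#' iteration cap 200.
#'
#' @param p a `degree_polynomial`.
#' @param alpha shift strictly inside [alpha_bounds()].
#' @param tol absolute bracket tolerance.
#' @param maxiter iteration cap.
#' @return object of class `zero_result` with fields `delta` (the zero),
#'   `alpha`, `residual` (`|P*(delta)|`) and `iterations`.
#' @examples
#' p <- degree_polynomial(c(3, 0, 0, 1, 2, 0, 1, 2))
#' unique_positive_zero(p, 4)$delta   # 0.683953
#' @export
unique_positive_zero <- function(p, alpha, tol = 1e-12, maxiter = 200L) {
  b <- alpha_bounds(p)
  if (alpha <= b[1L] || alpha >= b[2L]) {
    stop("alpha = ", alpha, " not in the admissible open interval (",
         b[1L], ", ", b[2L], ")")
  }
  f <- function(x) evaluate_modified(p, alpha, x)
  sol <- stats::uniroot(f, interval = c(0, 1), tol = tol, maxiter = maxiter,
                        f.lower = alpha - b[1L], f.upper = alpha - b[2L])
  if (is.na(sol$estim.prec)) stop("root iteration failed to converge")
  structure(list(delta = sol$root, alpha = alpha,
                 residual = abs(f(sol$root)),
                 iterations = as.integer(sol$iter)),
            class = "zero_result")
}

#' @export
print.zero_result <- function(x, ...) {
  cat("delta = ", formatC(x$delta, digits = 6, format = "f"),
      "  (alpha = ", x$alpha, ", residual ",
      formatC(x$residual, digits = 2, format = "e"), ", ",
      x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Sign changes in the coefficient sequence of the shifted polynomial
#'
#' Diagnostic used by the uniqueness argument: the number of strict sign
#' changes in the coefficients of `alpha - P(x)` read from degree 0 upward,
#' ignoring zeros. Equal to 1 for every admissible alpha.
#'
#' @inheritParams unique_positive_zero
#' @return integer count of sign changes.
#' @export
descartes_sign_changes <- function(p, alpha) {
  co <- c(alpha - p$coefficients[1L], -as.numeric(p$coefficients[-1L]))
  s <- sign(co[co != 0])
  sum(diff(s) != 0)
}
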