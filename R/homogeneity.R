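#' Zeros over all integer alpha candidates
#'
#' Solves `alpha - P(x) = 0` for every integer alpha strictly inside the
#' admissible interval. Because P is strictly increasing on (0, 1), the
#' zeros are strictly increasing in alpha.
#'
#' @param p a `degree_polynomial`.
#' @return object of class `zero_set`: list with `direction`, `alphas`
#'   (increasing integer candidates) and `deltas` (matching zeros).
#' @examples
#' zs <- zeros_over_candidates(degree_polynomial(c(1, 8)))
#' zs$deltas   # 1/8, 2/8, ..., 7/8
#' @export
zeros_over_candidates <- function(p) {
  sel <- select_alpha(p, "min_integer")
  if (length(sel$candidates) == 0L) {
    stop("no integer alpha candidates in (", sel$lower, ", ", sel$upper,
         "); use the midpoint alpha ", sel$alpha,
         " for a single zero (h is 0 for a singleton)")
  }
  deltas <- vapply(sel$candidates,
                   function(a) unique_positive_zero(p, a)$delta, numeric(1))
  structure(list(direction = p$direction,
                 alphas = as.integer(sel$candidates), deltas = deltas),
            class = "zero_set")
}

#' @export
print.zero_set <- function(x, ...) {
  cat("Zero set (", x$direction, "), k = ", length(x$alphas), "\n", sep = "")
  print(data.frame(alpha = x$alphas,
                   delta = formatC(x$deltas, digits = 6, format = "f")))
  invisible(x)
}

#' Homogeneity of a zero set
#'
#' `h(S) = (1 / (k (k - 1))) * sum_i sum_j |delta_i - delta_j|` over all
#' ordered pairs (the i = j terms vanish). Small h means the zero is nearly
#' insensitive to the choice of alpha. A singleton set gives h = 0 by
#' convention.
#'
#' @param x a `zero_set` or a numeric vector of zeros.
#' @return non-negative numeric score; bounded above by
#'   `max(deltas) - min(deltas)`.
#' @examples
#' homogeneity_score(c(0.1, 0.3))   # 0.2
#' @export
homogeneity_score <- function(x) {
  deltas <- if (inherits(x, "zero_set")) x$deltas else as.numeric(x)
  k <- length(deltas)
  if (k < 1L) stop("empty zero set")
  if (k == 1L) return(0)
  sum(abs(outer(deltas, deltas, "-"))) / (k * (k - 1))
}
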