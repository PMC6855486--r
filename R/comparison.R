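#' Shared admissible alpha range of two polynomials
#'
#' Intersection of the two open intervals `(a_0, sum(a_j))`; a shared alpha
#' makes the two zeros directly comparable.
#'
#' @param p_g,p_h `degree_polynomial` objects.
#' @return numeric `c(lower, upper)`; errors when the intersection is empty.
#' @export
shared_alpha_range <- function(p_g, p_h) {
  bg <- alpha_bounds(p_g)
  bh <- alpha_bounds(p_h)
  lo <- max(bg[1L], bh[1L])
  hi <- min(bg[2L], bh[2L])
  if (lo >= hi) {
    stop("no shared admissible alpha: intervals (", bg[1L], ", ", bg[2L],
         ") and (", bh[1L], ", ", bh[2L], ") do not overlap")
  }
  c(lower = unname(lo), upper = unname(hi))
}

#' Dominance bound for a linear polynomial against a general one
#'
#' When `P_G` is linear, its zero has the closed form
#' `delta = (alpha - a0_G) / a1_G`, and `delta(G) > delta(H)` is guaranteed
#' whenever `alpha` is strictly below `P_H`'s polynomial part evaluated at
#' that delta. This function returns that right-hand-side bound.
#'
#' @param p_g a linear `degree_polynomial` (`a1 x + a0`).
#' @param p_h any `degree_polynomial`.
#' @param alpha shift inside [shared_alpha_range()].
#' @return the bound `P_H-part(delta^alpha(G))`; the dominance condition is
#'   `alpha < bound`.
#' @export
linear_zero_bound <- function(p_g, p_h, alpha) {
  if (poly_degree(p_g) != 1L) {
    stop("the bound applies only when the first polynomial is linear")
  }
  rng <- shared_alpha_range(p_g, p_h)
  if (alpha <= rng[1L] || alpha >= rng[2L]) {
    stop("alpha = ", alpha, " outside the shared admissible range (",
         rng[1L], ", ", rng[2L], ")")
  }
  delta_g <- (alpha - p_g$coefficients[1L]) / p_g$coefficients[2L]
  evaluate_poly(p_h, delta_g)
}

#' Does linear dominance hold for every shared alpha?
#'
#' When the linear polynomial and the general one agree in `a0` and `a1`
#' and the general one has some coefficient of degree >= 2, the linear
#' polynomial's zero strictly exceeds the other's for every shared
#' admissible alpha.
#'
#' @inheritParams linear_zero_bound
#' @return logical scalar.
#' @export
linear_dominance_always <- function(p_g, p_h) {
  if (poly_degree(p_g) != 1L) {
    stop("the criterion applies only when the first polynomial is linear")
  }
  ah <- p_h$coefficients
  length(ah) >= 3L &&
    ah[1L] == p_g$coefficients[1L] &&
    ah[2L] == p_g$coefficients[2L] &&
    any(ah[-(1:2)] > 0L)
}

#' Coefficient-wise dominance
#'
#' TRUE iff `a_i^G <= a_i^H` for every i (shorter vector padded with
#' zeros) with strict inequality for at least one i >= 1. Then
#' `alpha - P_G(x) > alpha - P_H(x)` pointwise on (0, 1), hence
#' `delta(G) > delta(H)` for any shared admissible alpha.
#'
#' @param p_g,p_h `degree_polynomial` objects.
#' @return logical scalar.
#' @export
coefficient_dominance <- function(p_g, p_h) {
  k <- max(length(p_g$coefficients), length(p_h$coefficients))
  ag <- c(p_g$coefficients, integer(k))[seq_len(k)]
  ah <- c(p_h$coefficients, integer(k))[seq_len(k)]
  all(ag <= ah) && any(ag[-1L] < ah[-1L])
}

#' Compare the zeros of two polynomials at a shared alpha
#'
#' Solves both zeros directly and, where the hypotheses hold, applies the
#' linear-bound and coefficient-dominance criteria, recording whether each
#' prediction matches the computed ordering.
#'
#' @inheritParams linear_zero_bound
#' @param tol zeros closer than this are reported `"equal"`.
#' @return object of class `dominance_report`: list with `alpha`,
#'   `delta_g`, `delta_h`, `bound` (linear-case right-hand side or `NA`),
#'   `linear_condition_holds`, `coefficient_dominance`, `condition_holds`
#'   (either criterion certifies `delta_g > delta_h`) and `ordering`
#'   (`"G_greater"`, `"H_greater"` or `"equal"`).
#' @examples
#' p5 <- degree_polynomial(c(4, 2, 1, 1))
#' p6 <- degree_polynomial(c(6, 3, 2, 2))
#' compare_zeros(p5, p6, 7)$ordering
#' @export
compare_zeros <- function(p_g, p_h, alpha, tol = 1e-9) {
  rng <- shared_alpha_range(p_g, p_h)
  if (alpha <= rng[1L] || alpha >= rng[2L]) {
    stop("alpha = ", alpha, " outside the shared admissible range (",
         rng[1L], ", ", rng[2L], ")")
  }
  delta_g <- if (poly_degree(p_g) == 1L) {
    (alpha - p_g$coefficients[1L]) / p_g$coefficients[2L]
  } else {
    unique_positive_zero(p_g, alpha)$delta
  }
  delta_h <- if (poly_degree(p_h) == 1L) {
    (alpha - p_h$coefficients[1L]) / p_h$coefficients[2L]
  } else {
    unique_positive_zero(p_h, alpha)$delta
  }
  bound <- if (poly_degree(p_g) == 1L) linear_zero_bound(p_g, p_h, alpha)
           else NA_real_
  lin <- !is.na(bound) && alpha < bound
  dom <- coefficient_dominance(p_g, p_h)
  ordering <- if (abs(delta_g - delta_h) < tol) "equal"
              else if (delta_g > delta_h) "G_greater" else "H_greater"
  structure(list(alpha = alpha, delta_g = delta_g, delta_h = delta_h,
                 bound = bound, linear_condition_holds = lin,
                 coefficient_dominance = dom,
                 condition_holds = lin || dom, ordering = ordering),
            class = "dominance_report")
}

#' @export
print.dominance_report <- function(x, ...) {
  cat("Zero comparison at alpha = ", x$alpha, "\n", sep = "")
  cat("  delta(G) = ", formatC(x$delta_g, digits = 6, format = "f"),
      ", delta(H) = ", formatC(x$delta_h, digits = 6, format = "f"), "\n",
      sep = "")
  if (!is.na(x$bound)) {
    cat("  linear bound = ", formatC(x$bound, digits = 3, format = "f"),
        " (condition ", if (x$linear_condition_holds) "holds" else "fails",
        ")\n", sep = "")
  }
  cat("  coefficient dominance: ", x$coefficient_dominance, "\n", sep = "")
  cat("  ordering: ", x$ordering, "\n", sep = "")
  invisible(x)
}
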