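# Shared generators and the independent grid-scan oracle.

# absolute-difference assertion for values the reference prints to a fixed
# number of decimals (printed values may be truncated, not rounded)
expect_near <- function(actual, expected, tol = 1e-6) {
  expect_lt(max(abs(actual - expected)), tol)
}

# random degree polynomial with an admissible alpha range (some a_j > 0, j >= 1)
random_polynomial <- function(k_max = 8L, coef_max = 9L) {
  k <- sample(1:k_max, 1L)
  a <- sample(0:coef_max, k + 1L, replace = TRUE)
  a[k + 1L] <- sample(1:coef_max, 1L)                 # leading term positive
  if (all(a[-1L] == 0L)) a[2L] <- sample(1:coef_max, 1L)
  degree_polynomial(a)
}

# uniform admissible alpha for a polynomial (real-valued)
random_alpha <- function(p) {
  b <- alpha_bounds(p)
  runif(1, b[1L], b[2L])
}

# independent oracle: bracket the zero of alpha - P on a fixed grid over (0, 1)
# and return the sign-change interval; accuracy = grid spacing
grid_scan_bracket <- function(p, alpha, n_grid = 1e6L) {
  x <- seq(0, 1, length.out = n_grid + 1L)
  fx <- alpha - evaluate_poly(p, x)
  i <- which(fx[-length(fx)] > 0 & fx[-1L] <= 0)[1L]
  c(x[i], x[i + 1L])
}

# random small weakly connected ER digraph for property tests
random_digraph <- function() {
  n <- sample(3:10, 1L)
  m <- sample(seq.int(n - 1L, n * (n - 1L)), 1L)
  erdos_renyi_digraph(n, c(m, m))
}

# structural validator for hierarchical graphs: non-empty levels, all edges
# strictly downward in level number (toward the root level 0), root level
# has out-degree 0, every non-root vertex has out-degree >= 1
expect_valid_hierarchy <- function(g, levels = 4L) {
  lev <- igraph::V(g)$level
  expect_setequal(unique(lev), 0:(levels - 1L))
  el <- igraph::as_edgelist(g, names = FALSE)
  expect_true(all(lev[el[, 1]] > lev[el[, 2]]))
  outd <- igraph::degree(g, mode = "out")
  expect_true(all(outd[lev == 0L] == 0L))
  expect_true(all(outd[lev > 0L] >= 1L))
}
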