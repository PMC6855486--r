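ex <- example_polynomials()

test_that("degree polynomials are built from degree-class counts", {
  gs <- example_graphs()
  expect_equal(build_polynomial(gs$g2, "out")$coefficients, c(1L, 8L))
  expect_equal(build_polynomial(gs$g2, "in")$coefficients, c(1L, 8L))
  expect_equal(build_polynomial(gs$g3, "out")$coefficients,
               c(8L, rep(0L, 7L), 1L))
  expect_equal(build_polynomial(gs$g4, "out")$coefficients, c(1L, 8L))
  expect_equal(build_polynomial(gs$g4, "in")$coefficients,
               c(7L, 1L, 0L, 0L, 0L, 0L, 0L, 1L))
})

test_that("constructor validates and normalises coefficients", {
  expect_error(degree_polynomial(c(-1, 2)), "non-negative")
  expect_error(degree_polynomial(c(1.5, 2)), "non-negative")
  expect_error(degree_polynomial(numeric(0)), "empty")
  expect_equal(degree_polynomial(c(1, 2, 0, 0))$coefficients, c(1L, 2L))
  expect_equal(poly_degree(degree_polynomial(c(0, 0, 3))), 2L)
})

test_that("evaluation is Horner-consistent and vectorised", {
  set.seed(21)
  for (rep in 1:20) {
    p <- random_polynomial()
    x <- runif(5)
    direct <- vapply(x, function(xi)
      sum(p$coefficients * xi^(seq_along(p$coefficients) - 1L)), numeric(1))
    expect_equal(evaluate_poly(p, x), direct, tolerance = 1e-12)
  }
  lin <- degree_polynomial(c(1, 8))
  expect_equal(evaluate_poly(lin, 0), 1)
  expect_equal(evaluate_poly(lin, 1), 9)
  expect_equal(evaluate_modified(lin, 2, 0.125), 0)
})

test_that("alpha bounds are (a0, sum of coefficients)", {
  expect_equal(unname(alpha_bounds(ex$g1_out)), c(3, 9))
  expect_equal(unname(alpha_bounds(ex$g3_out)), c(8, 9))
  cycle9 <- degree_polynomial(c(0, 9))
  expect_equal(unname(alpha_bounds(cycle9)), c(0, 9))
  expect_error(alpha_bounds(degree_polynomial(5)), "no admissible alpha")
})

test_that("alpha selection follows min-integer with midpoint fallback", {
  s1 <- select_alpha(ex$g1_out)
  expect_equal(s1$candidates, 4:8)
  expect_equal(s1$alpha, 4)
  expect_equal(s1$policy, "min_integer")

  s3 <- select_alpha(ex$g3_out)
  expect_equal(s3$candidates, integer(0))
  expect_equal(s3$alpha, 8.5)
  expect_equal(s3$policy, "midpoint")

  s2 <- select_alpha(ex$g2_out)
  expect_equal(s2$candidates, 2:8)
  expect_equal(s2$alpha, 2)

  se <- select_alpha(ex$g2_out, "explicit", value = 4.5)
  expect_equal(se$alpha, 4.5)
  expect_error(select_alpha(ex$g2_out, "explicit", value = 9), "\\(1, 9\\)")
  expect_error(select_alpha(ex$g2_out, "explicit"), "requires a value")
})

test_that("the solver reproduces the worked-example zeros", {
  expect_near(unique_positive_zero(ex$g1_out, 4)$delta, 0.683953)
  expect_near(unique_positive_zero(ex$g1_in, 3)$delta, 0.608309)
  expect_equal(unique_positive_zero(ex$g2_out, 2)$delta, 0.125,
               tolerance = 1e-9)
  # monomial closed form ((alpha - a0)/a_k)^(1/k)
  expect_equal(unique_positive_zero(ex$g3_out, 8.5)$delta, 0.5^(1 / 8),
               tolerance = 1e-9)
  z <- unique_positive_zero(ex$g1_out, 4)
  expect_lt(z$residual, 1e-9)
  expect_error(unique_positive_zero(ex$g1_out, 3), "admissible")
  expect_error(unique_positive_zero(ex$g1_out, 9), "admissible")
})

test_that("closed forms agree with the solver for linear and monomial cases", {
  set.seed(22)
  for (rep in 1:20) {
    a0 <- sample(0:5, 1); a1 <- sample(1:9, 1)
    p <- degree_polynomial(c(a0, a1))
    alpha <- random_alpha(p)
    expect_equal(unique_positive_zero(p, alpha)$delta, (alpha - a0) / a1,
                 tolerance = 1e-9)
    k <- sample(2:8, 1); ak <- sample(1:9, 1)
    pm <- degree_polynomial(c(a0, rep(0, k - 1), ak))
    am <- random_alpha(pm)
    expect_equal(unique_positive_zero(pm, am)$delta,
                 ((am - a0) / ak)^(1 / k), tolerance = 1e-9)
  }
})

test_that("shifted coefficient sequence has exactly one sign change", {
  set.seed(23)
  for (rep in 1:100) {
    p <- random_polynomial()
    expect_equal(descartes_sign_changes(p, random_alpha(p)), 1L)
  }
})

test_that("the zero is strictly increasing in alpha", {
  set.seed(24)
  for (rep in 1:20) {
    p <- random_polynomial()
    cand <- select_alpha(p)$candidates
    if (length(cand) < 2) next
    deltas <- vapply(cand, function(a) unique_positive_zero(p, a)$delta,
                     numeric(1))
    expect_true(all(diff(deltas) > 0))
  }
})

test_that("solver agrees with the grid-scan bracketing oracle", {
  set.seed(25)
  for (rep in 1:20) {
    p <- random_polynomial()
    alpha <- random_alpha(p)
    br <- grid_scan_bracket(p, alpha)
    d <- unique_positive_zero(p, alpha)$delta
    expect_gte(d, br[1] - 1e-12)
    expect_lte(d, br[2] + 1e-12)
  }
})

test_that("the zero varies continuously with alpha", {
  set.seed(26)
  eps <- 1e-6
  for (rep in 1:20) {
    p <- random_polynomial()
    b <- alpha_bounds(p)
    alpha <- runif(1, b[1] + 0.1, b[2] - 0.1)
    d1 <- unique_positive_zero(p, alpha)$delta
    d2 <- unique_positive_zero(p, alpha + eps)$delta
    expect_lt(abs(d2 - d1), 1e-3)
    expect_gt(d2, d1)   # monotone as well as close
  }
})

test_that("polynomial JSON fixtures round-trip and match the in-code set", {
  p <- ex$g1_out
  tmp <- tempfile(fileext = ".json")
  write_polynomial_json(p, tmp)
  q <- read_polynomial_json(tmp)
  expect_equal(q$coefficients, p$coefficients)
  expect_equal(q$direction, p$direction)
  for (nm in names(ex)) {
    path <- system.file("extdata", paste0(nm, ".json"), package = "degpoly")
    expect_true(nzchar(path))
    expect_equal(read_polynomial_json(path)$coefficients,
                 ex[[nm]]$coefficients)
  }
})
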