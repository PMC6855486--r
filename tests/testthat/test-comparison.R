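ex <- example_polynomials()

test_that("shared alpha range is the interval intersection", {
  expect_equal(unname(shared_alpha_range(ex$g4_out, ex$hier23_out)), c(6, 9))
  expect_equal(unname(shared_alpha_range(ex$g5_out, ex$g6_out)), c(6, 8))
  expect_equal(unname(shared_alpha_range(ex$g1_out, ex$g1_out)),
               unname(alpha_bounds(ex$g1_out)))
  p_low <- degree_polynomial(c(0, 2))   # range (0, 2)
  p_high <- degree_polynomial(c(5, 4))  # range (5, 9)
  expect_error(shared_alpha_range(p_low, p_high), "do not overlap")
})

test_that("linear-dominance bound reproduces the worked demo", {
  b <- linear_zero_bound(ex$g4_out, ex$hier23_out, 7)
  expect_equal(round(b, 3), 14.920)
  expect_true(7 < b)
  expect_error(linear_zero_bound(ex$g1_out, ex$hier23_out, 7), "linear")
  expect_error(linear_zero_bound(ex$g4_out, ex$hier23_out, 20), "shared")
  # the bound is P_H's polynomial part at the linear zero (alpha - a0)/a1
  expect_equal(b, evaluate_poly(ex$hier23_out, (7 - 1) / 8), tolerance = 1e-12)
  # as alpha approaches a0_G the linear zero vanishes and the bound tends
  # to a0_H: check with a pair whose shared range reaches down to a0_G
  p_g <- degree_polynomial(c(1, 8))
  p_h <- degree_polynomial(c(1, 2, 3))
  expect_equal(linear_zero_bound(p_g, p_h, 1 + 1e-9), 1, tolerance = 1e-8)
})

test_that("matching low-order coefficients guarantee linear dominance", {
  lin <- degree_polynomial(c(1, 8))
  expect_true(linear_dominance_always(lin, degree_polynomial(c(1, 8, 1))))
  expect_false(linear_dominance_always(lin, degree_polynomial(c(1, 8))))
  expect_false(linear_dominance_always(lin, degree_polynomial(c(2, 8, 1))))
  set.seed(61)
  for (rep in 1:20) {
    a0 <- sample(0:4, 1); a1 <- sample(2:8, 1)
    k <- sample(2:6, 1)
    tail <- sample(0:3, k - 1, replace = TRUE)
    tail[k - 1] <- sample(1:3, 1)
    p_g <- degree_polynomial(c(a0, a1))
    p_h <- degree_polynomial(c(a0, a1, tail))
    expect_true(linear_dominance_always(p_g, p_h))
    rng <- shared_alpha_range(p_g, p_h)
    for (alpha in runif(5, rng[1], rng[2])) {
      rep_out <- compare_zeros(p_g, p_h, alpha)
      expect_gt(rep_out$delta_g, rep_out$delta_h)
    }
  }
})

test_that("coefficient dominance is decided coefficient-wise", {
  expect_true(coefficient_dominance(ex$g5_out, ex$g6_out))
  expect_false(coefficient_dominance(ex$g5_out, ex$g5_out))
  expect_false(coefficient_dominance(ex$g6_out, ex$g5_out))
  # equal except a higher-degree surplus, with length padding
  expect_true(coefficient_dominance(degree_polynomial(c(2, 3)),
                                    degree_polynomial(c(2, 3, 1))))
  # a0 alone larger does not qualify (needs a strict i >= 1 increase)
  expect_false(coefficient_dominance(degree_polynomial(c(2, 3)),
                                     degree_polynomial(c(4, 3))))
})

test_that("coefficient dominance implies the zero ordering", {
  set.seed(62)
  for (rep in 1:30) {
    p_g <- random_polynomial(k_max = 6)
    bump <- sample(0:2, length(p_g$coefficients), replace = TRUE)
    if (all(bump[-1] == 0)) bump[2] <- 1
    p_h <- degree_polynomial(p_g$coefficients + bump)
    expect_true(coefficient_dominance(p_g, p_h))
    rng <- tryCatch(shared_alpha_range(p_g, p_h), error = function(e) NULL)
    if (is.null(rng)) next
    alpha <- runif(1, rng[1], rng[2])
    rep_out <- compare_zeros(p_g, p_h, alpha)
    expect_equal(rep_out$ordering, "G_greater")
  }
})

test_that("direct comparison reproduces the printed demo zeros", {
  r56 <- compare_zeros(ex$g5_out, ex$g6_out, 7)
  expect_near(r56$delta_g, 0.843734)
  expect_near(r56$delta_h, 0.271069)
  expect_equal(r56$ordering, "G_greater")
  expect_true(r56$condition_holds)

  r4h <- compare_zeros(ex$g4_out, ex$hier23_out, 7)
  expect_identical(r4h$delta_g, (7 - 1) / 8)   # exact linear closed form
  expect_near(r4h$delta_h, 0.099995)
  expect_equal(r4h$ordering, "G_greater")
  expect_true(r4h$linear_condition_holds)

  same <- compare_zeros(ex$g5_out, ex$g5_out, 7)
  expect_equal(same$ordering, "equal")
})

test_that("comparison is antisymmetric", {
  set.seed(63)
  for (rep in 1:20) {
    p_g <- random_polynomial(); p_h <- random_polynomial()
    rng <- tryCatch(shared_alpha_range(p_g, p_h), error = function(e) NULL)
    if (is.null(rng)) next
    alpha <- runif(1, rng[1], rng[2])
    f <- compare_zeros(p_g, p_h, alpha)
    r <- compare_zeros(p_h, p_g, alpha)
    flip <- c(G_greater = "H_greater", H_greater = "G_greater",
              equal = "equal")
    expect_equal(r$ordering, unname(flip[f$ordering]))
  }
})
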