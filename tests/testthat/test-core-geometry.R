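test_that("graded basis enumeration matches the coefficient-count formula", {
  for (r in 1:4) for (d in 0:4) {
    b <- basis_enumerate(r, d)
    expect_equal(nrow(b), n_coefficients(r, d))
    expect_equal(nrow(b), choose(r + d, r))
    expect_equal(b[1, ], rep(0L, r))           # constant term first
    expect_true(all(diff(rowSums(b)) >= 0))    # graded by total degree
  }
  expect_equal(nrow(basis_enumerate(6, 6)), n_coefficients(6, 6))
  # within-degree order: lexicographically descending (k1^2, k1 k2, k2^2)
  expect_equal(basis_enumerate(2, 2),
               rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L),
                     c(2L, 0L), c(1L, 1L), c(0L, 2L)))
  expect_equal(basis_enumerate(1, 2), cbind(0:2))
  expect_equal(n_coefficients(8, 2), 45)
  expect_equal(n_coefficients(5, 0), 1)
  expect_error(basis_enumerate(0, 2), "positive")
  expect_error(n_coefficients(2, -1), "nonnegative")
})

test_that("monomial moments are exact and match Monte-Carlo integration", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  expect_equal(monomial_integral(u2, c(0, 0)), 1)
  expect_equal(monomial_integral(u2, c(1, 1)), 0.25)
  B <- hyperrectangle(c(0.0005, 0), c(0.001, 2))
  expect_equal(monomial_integral(B, c(1, 0)), 7.5e-7)
  set.seed(4)
  for (i in 1:5) {
    box <- hyperrectangle(runif(2, -2, 0), runif(2, 0.5, 3))
    alpha <- sample(0:3, 2, replace = TRUE)
    mc <- mc_monomial_integral(box, alpha, seed = i)
    expect_lt(abs(monomial_integral(box, alpha) - mc$value), 3 * mc$se + 1e-12)
  }
  expect_error(monomial_integral(u2, c(1, 2, 3)), "dimension")
})

test_that("polynomial evaluation is linear and respects the basis order", {
  one <- dense_polynomial(2, 2, c(1, 0, 0, 0, 0, 0))
  expect_equal(poly_eval(one, c(13.7, -2)), 1)
  p <- dense_polynomial(1, 2, c(1, 0, -1))  # 1 - x^2
  expect_equal(poly_eval(p, 0.5), 0.75)
  set.seed(7)
  q <- dense_polynomial(2, 3, rnorm(10))
  s <- dense_polynomial(2, 3, rnorm(10))
  pts <- matrix(runif(10, -1, 2), 5, 2)
  comb <- dense_polynomial(2, 3, 2.5 * q$coefficients - 0.7 * s$coefficients)
  expect_equal(poly_eval(comb, pts),
               2.5 * poly_eval(q, pts) - 0.7 * poly_eval(s, pts))
  expect_error(poly_eval(p, c(1, 2)), "dimension")
  expect_error(dense_polynomial(2, 2, 1:5), "coefficients")
})

test_that("affine composition is exact at coefficient level and invertible", {
  p <- dense_polynomial(1, 1, c(0, 1))  # x
  q <- affine_compose(p, affine_map(0.5, 0))
  expect_equal(q$coefficients, c(0, 0.5))
  ident <- affine_map(c(1, 1), c(0, 0))
  set.seed(8)
  p3 <- dense_polynomial(2, 3, rnorm(10))
  expect_equal(affine_compose(p3, ident)$coefficients, p3$coefficients)
  m <- affine_map(c(1.7, -0.4), c(0.3, 2))
  q3 <- affine_compose(p3, m)
  pts <- matrix(rnorm(200), 100, 2)
  expect_lt(max(abs(poly_eval(q3, pts) - poly_eval(p3, affine_apply(m, pts)))),
            1e-10)
  back <- affine_compose(q3, affine_invert(m))
  expect_lt(max(abs(back$coefficients - p3$coefficients)), 1e-9)
  expect_error(affine_map(c(1, 0), c(0, 0)), "invertible")
})

test_that("hyperrectangles validate, measure and bisect correctly", {
  expect_error(hyperrectangle(c(0, 0), c(1, 0)), "degenerate")
  expect_error(hyperrectangle(0, c(1, 2)), "length")
  B <- hyperrectangle(c(0, 0), c(2, 1))
  expect_equal(box_volume(B), 2)
  expect_equal(box_midpoint(B), c(1, 0.5))
  expect_true(box_contains(B, c(2, 1)))   # closed: boundary is inside
  expect_false(box_contains(B, c(2.1, 0.5)))
  S <- hyperrectangle(c(0, 0), c(1, 1))
  expect_equal(box_normalized_volume(S, B), 0.5)
  halves <- box_bisect(B, 1)
  expect_equal(halves[[1]]$upper, c(1, 1))
  expect_equal(halves[[2]]$lower, c(1, 0))
})

test_that("polynomial and box serialization round-trips exactly", {
  set.seed(9)
  p <- dense_polynomial(3, 2, rnorm(10) * 10^runif(10, -8, 6))
  f <- tempfile(fileext = ".json")
  write_polynomial_json(p, f)
  q <- read_polynomial_json(f)
  expect_identical(q$coefficients, p$coefficients)
  expect_identical(q$r, p$r)
  b <- hyperrectangle(c(0.0005, 0), c(0.001, 2))
  fb <- tempfile(fileext = ".json")
  write_box_json(b, fb)
  b2 <- read_box_json(fb)
  expect_identical(b2$lower, b$lower)
  expect_identical(b2$upper, b$upper)
  unlink(c(f, fb))
})
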