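test_that("1-D fits reach the analytic optima", {
  # B = [-1,1], K = [-0.5,0.5]: the degree-2 optimum is p = (4/3)(1 - x^2)
  # with integral 16/9 (active constraints at x = +-0.5 and +-1; the
  # certificate is exact with constant multiplier 4/3)
  B <- hyperrectangle(-1, 1)
  f <- fit_pss_from_rectangles(B, list(hyperrectangle(-0.5, 0.5)), 2)
  expect_equal(f$solver_status, "optimal")
  expect_lt(abs(f$objective_value - 16 / 9), 1e-5)
  expect_lt(max(abs(f$polynomial$coefficients - c(4 / 3, 0, -4 / 3))), 1e-4)
  # single point at 0: minimize 2 c0 + (2/3) c2 with p(0) >= 1, p >= 0 on B
  # gives p = 1 - x^2, integral 4/3
  g <- fit_pss_from_points(B, matrix(0), 2)
  expect_lt(abs(g$objective_value - 4 / 3), 1e-5)
  # K = B forces p identically 1: the objective is Vol(B)
  B01 <- hyperrectangle(0, 1)
  h <- fit_pss_from_rectangles(B01, list(B01), 2)
  expect_lt(abs(h$objective_value - 1), 1e-5)
  expect_lt(max(abs(h$polynomial$coefficients - c(1, 0, 0))), 1e-3)
})

test_that("fits contain their targets (K inside U(p)) and verify cleanly", {
  set.seed(31)
  for (i in 1:4) {
    B <- hyperrectangle(c(0, 0), runif(2, 1, 3))
    lo <- runif(2, 0.05, 0.4) * B$upper
    hi <- lo + runif(2, 0.2, 0.5) * (B$upper - lo)
    K <- list(hyperrectangle(lo, hi))
    f <- fit_pss_from_rectangles(B, K, 2)
    v <- verify_fit(f, B, K)
    expect_lt(v$max_violation_K, 1e-6)
    expect_lt(v$max_violation_B, 1e-6)
  }
  # the exact analytic optimum has zero violations
  p <- dense_polynomial(1, 2, c(4 / 3, 0, -4 / 3))
  pss <- structure(list(polynomial = p, threshold = 1,
                        box = hyperrectangle(-1, 1)),
                   class = "pss_representation")
  v <- verify_fit(pss, K = list(hyperrectangle(-0.5, 0.5)))
  expect_equal(v$max_violation_B, 0)
  expect_lt(v$max_violation_K, 1e-9)
  # corrupted coefficients are flagged
  bad <- pss
  bad$polynomial <- dense_polynomial(1, 2, c(0.5, 0, -4 / 3))
  vb <- verify_fit(bad, K = list(hyperrectangle(-0.5, 0.5)))
  expect_gt(vb$max_violation_K, 0.1)
  expect_false(vb$ok)
})

test_that("objective is non-increasing in the fit degree", {
  B <- hyperrectangle(-1, 1)
  K <- list(hyperrectangle(-0.5, 0.5))
  objs <- vapply(c(2, 4, 6), function(d)
    fit_pss_from_rectangles(B, K, d)$objective_value, 0)
  expect_true(all(diff(objs) <= 1e-5))
})

test_that("rescaled and direct fits agree (affine invariance)", {
  B <- hyperrectangle(c(0.2, 1), c(1.5, 3))
  K <- list(hyperrectangle(c(0.4, 1.5), c(0.9, 2.2)))
  f1 <- fit_pss_from_rectangles(B, K, 2, pss_options(rescale = TRUE))
  f2 <- fit_pss_from_rectangles(B, K, 2, pss_options(rescale = FALSE))
  expect_lt(abs(f1$objective_value - f2$objective_value) /
              abs(f1$objective_value), 1e-4)
  pts <- as.matrix(expand.grid(seq(0.2, 1.5, length.out = 9),
                               seq(1, 3, length.out = 9)))
  dimnames(pts) <- NULL
  m1 <- poly_eval(f1$polynomial, pts) >= 1 - 1e-4
  m2 <- poly_eval(f2$polynomial, pts) >= 1 - 1e-4
  expect_equal(m1, m2)
})

test_that("point-mode fits in 8 parameters return all 45 coefficients", {
  B8 <- hyperrectangle(c(1, 0, 0.0005, 0, 1, 1, 40, 0),
                       c(4, 2, 0.001, 2, 4, 3, 50, 2))
  pts <- sample_distribution(distribution_spec("uniform", B8), 60, seed = 32)
  f <- fit_pss_from_points(B8, pts, 2)
  expect_length(f$polynomial$coefficients, 45L)
  v <- verify_fit(f, B8, pts)
  expect_lt(v$max_violation_K, 1e-6)
})

test_that("sampled positivity mode solves the relaxed linear program", {
  B <- hyperrectangle(-1, 1)
  f_sos <- fit_pss_from_points(B, matrix(0), 2)
  f_lp <- fit_pss_from_points(B, matrix(0), 2, positivity = "sampled")
  # sampling p >= 0 relaxes the certificate: the LP value cannot exceed
  # the SOS value (up to solver accuracy), and p(0) >= 1 still holds
  expect_lte(f_lp$objective_value, f_sos$objective_value + 1e-5)
  expect_gte(poly_eval(f_lp$polynomial, 0), 1 - 1e-6)
  expect_equal(f_lp$solver_info$n_pos, 1000L)
  # p == 1 is always feasible, so any point configuration stays solvable
  pts <- matrix(c(-0.9, 0.9), ncol = 1)
  f2 <- fit_pss_from_points(B, pts, 2)
  expect_lte(f2$objective_value, 2 + 1e-6)
})

test_that("fit preconditions are enforced", {
  B <- hyperrectangle(-1, 1)
  expect_error(fit_pss_from_rectangles(B, list(), 2), "empty target")
  expect_error(fit_pss_from_rectangles(B, list(hyperrectangle(0, 2)), 2),
               "contained in B")
  expect_error(fit_pss_from_rectangles(B, list(hyperrectangle(-0.5, 0.5)), 3),
               "even")
  expect_error(fit_pss_from_points(B, matrix(2), 2), "inside B")
  expect_error(fit_pss_from_points(B, matrix(0, 0, 1), 2), "empty target")
})

test_that("membership of the printed S-system superlevel polynomial", {
  p <- ssystem_printed_pss()
  # direct evaluation of the printed coefficients at the bistable point
  expect_equal(poly_eval(p, c(5, 3, 12)), 1.084084, tolerance = 1e-6)
  pss <- structure(list(polynomial = p, threshold = 1,
                        box = hyperrectangle(c(3, 1, 10), c(7, 5, 14))),
                   class = "pss_representation")
  expect_true(pss_member(pss, c(5, 3, 12)))
  expect_warning(res <- pss_member(pss, c(100, 3, 12)), "outside")
  expect_false(res)
  # closed superlevel set: boundary value exactly 1 is a member
  pb <- structure(list(polynomial = dense_polynomial(1, 2, c(1, 0, -1)),
                       threshold = 1, box = hyperrectangle(-1, 1)),
                  class = "pss_representation")
  expect_true(pss_member(pb, 0))
  pz <- structure(list(polynomial = dense_polynomial(1, 2, c(0, 0, 0)),
                       threshold = 1, box = hyperrectangle(-1, 1)),
                  class = "pss_representation")
  expect_false(pss_member(pz, 0.3))
})

test_that("superlevel volume estimates match analytic values", {
  p <- dense_polynomial(1, 2, c(4 / 3, 0, -4 / 3))  # U(p) = [-0.5, 0.5]
  pss <- structure(list(polynomial = p, threshold = 1,
                        box = hyperrectangle(-1, 1)),
                   class = "pss_representation")
  v <- superlevel_volume(pss, 20000, seed = 33)
  expect_lt(abs(v - 0.5), 4 * attr(v, "standard_error"))
  one <- structure(list(polynomial = dense_polynomial(1, 2, c(1, 0, 0)),
                        threshold = 1, box = hyperrectangle(-1, 1)),
                   class = "pss_representation")
  expect_equal(as.numeric(superlevel_volume(one, 1000, seed = 1)), 1)
  zero <- structure(list(polynomial = dense_polynomial(1, 2, c(0, 0, 0)),
                         threshold = 1, box = hyperrectangle(-1, 1)),
                    class = "pss_representation")
  expect_equal(as.numeric(superlevel_volume(zero, 1000, seed = 1)), 0)
})
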