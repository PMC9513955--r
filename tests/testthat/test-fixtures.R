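test_that("quintic fixture counts strictly positive roots only", {
  qs <- quintic_fixture()
  expect_equal(count_positive_solutions(qs, c(0.75, 8.5)), 2L)
  # at k2 = 6.25 the constant term vanishes exactly: the root at 0 must not
  # be counted, so the count equals that of the deflated polynomial
  co <- quintic_coefficients(c(0.75, 6.25))
  expect_identical(co[1], 0)
  expect_equal(count_positive_roots_univariate(co),
               count_positive_roots_univariate(co[-1]))
  # uniform expectation on B1 is 2 exactly (count is invariant there)
  B1 <- hyperrectangle(c(0.5, 8), c(1, 9))
  sr <- build_sampling_representation(qs, B1, 100, seed = 2)
  expect_true(all(sr$counts == 2L))
})

test_that("S-system back-map sends every counted root to a steady state", {
  ss <- ssystem_fixture()
  set.seed(13)
  K <- cbind(runif(100, 3, 7), runif(100, 1, 5), runif(100, 10, 14))
  worst <- 0
  for (i in seq_len(nrow(K))) {
    k <- K[i, ]
    for (y in ss$positive_roots(k)) {
      res <- ss$residual(ss$back_map(y, k), k)
      worst <- max(worst, max(abs(res)))
    }
  }
  expect_lt(worst, 1e-6)
  expect_error(ss$coefficients(c(-1, 3, 12)), "positive")
})

test_that("LacI-TetR elimination reproduces the full 12-equation system", {
  ls <- lacitetr_fixture()
  set.seed(14)
  worst <- 0; all_counts <- integer(0)
  for (i in 1:20) {
    k <- runif(2, 0.005, 0.1)
    v <- ls$positive_roots(k)
    all_counts <- c(all_counts, length(v))
    for (vv in v) {
      x <- ls$recover_state(vv, k)
      expect_true(all(x > 0))
      worst <- max(worst, max(abs(ls$residual(x, k))))
    }
  }
  expect_lt(worst, 1e-6)
  expect_true(all(all_counts %in% c(1L, 2L, 3L)))
  expect_error(ls$positive_roots(c(0, 0.05)), "positive")
})

test_that("LacI-TetR counts agree with brute-force bracketing", {
  ls <- lacitetr_fixture()
  set.seed(15)
  for (i in 1:10) {
    k <- runif(2, 0.01, 0.1)
    co <- ls$poly_in_v(k)
    f <- function(v) { s <- 0; for (j in rev(seq_along(co))) s <- s * v + co[j]; s }
    expect_equal(count_positive_roots_univariate(co),
                 bracket_count(f, 1e-8, 4))
  }
})

test_that("autoreg cubic reduction satisfies the motif steady-state equations", {
  ar <- autoreg_fixture()
  set.seed(16)
  worst <- 0
  for (i in 1:50) {
    k <- c(runif(1, 5e-4, 1e-3), runif(1, 0.05, 2))
    roots <- positive_roots_univariate(ar$cubic(k))
    for (x2 in roots) {
      x <- ar$recover_state(x2, k)
      expect_true(all(x >= 0))
      worst <- max(worst, max(abs(ar$residual(x, k))))
    }
  }
  expect_lt(worst, 1e-6)
  expect_equal(count_positive_solutions(ar, c(0.0005, 1.5)), 3L)
})

test_that("synthetic region oracle has exact closed-form expectations", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  half <- hyperrectangle(c(0, 0), c(0.5, 1))
  orc <- synthetic_region_oracle(list(list(box = half, value = 3)),
                                 background = 1, box = u2)
  expect_equal(orc$exact_expectation(u2), 2)
  inside <- hyperrectangle(c(0.1, 0.1), c(0.4, 0.9))
  expect_equal(orc$exact_expectation(inside), 3)
  expect_equal(count_positive_solutions(orc$system, c(0.25, 0.5)), 3L)
  expect_equal(count_positive_solutions(orc$system, c(0.75, 0.5)), 1L)
  # overlapping cells are rejected
  expect_error(synthetic_region_oracle(
    list(list(box = half, value = 3),
         list(box = hyperrectangle(c(0.25, 0), c(0.75, 1)), value = 5)),
    background = 1, box = u2), "disjoint")
  # Monte-Carlo expectation agrees with the closed form on random sub-boxes
  set.seed(17)
  for (i in 1:20) {
    lo <- runif(2, 0, 0.6); hi <- lo + runif(2, 0.2, 0.39)
    sb <- hyperrectangle(lo, hi)
    est <- expected_count(orc$system, distribution_spec("uniform", sb),
                          400, seed = i)
    tolr <- 3 * max(est$standard_error, 1e-12)
    expect_lt(abs(est$value - orc$exact_expectation(sb)), tolr + 1e-9)
  }
})
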