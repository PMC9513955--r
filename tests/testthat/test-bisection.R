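test_that("two-value bisection recovers a dyadic region exactly", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  half <- hyperrectangle(c(0, 0), c(0.5, 1))
  orc <- synthetic_region_oracle(list(list(box = half, value = 3)),
                                 background = 1, box = u2)
  oracle <- function(cell, dist = NULL) orc$exact_expectation(cell)
  dec <- two_value_bisection(oracle, u2, 1, 3,
                             bisection_config(eps = 0.5, delta = 0.01))
  expect_length(dec$labels[["3"]], 1L)
  expect_length(dec$labels[["1"]], 1L)
  expect_equal(dec$labels[["3"]][[1]]$upper, c(0.5, 1))
  expect_equal(dec$labels[["1"]][[1]]$lower, c(0.5, 0))
  expect_equal(dec$oracle_calls, 3L)  # root + two conclusive halves

  # finer dyadic region: exact recovery once eps is below the cell width
  quarter <- hyperrectangle(c(0.25, 0.5), c(0.5, 0.75))
  orc2 <- synthetic_region_oracle(list(list(box = quarter, value = 3)),
                                  background = 1, box = u2)
  oracle2 <- function(cell, dist = NULL) orc2$exact_expectation(cell)
  dec2 <- two_value_bisection(oracle2, u2, 1, 3,
                              bisection_config(eps = 0.2, delta = 0.01))
  sel <- decomposition_to_K(dec2, 2)
  expect_gt(length(sel), 0L)
  vol3 <- sum(vapply(sel, box_volume, 0))
  expect_equal(vol3, box_volume(quarter), tolerance = 1e-12)
  for (cl in sel) expect_true(box_is_subset(cl, quarter))
})

test_that("bisection leaves partition the box", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  orc <- synthetic_region_oracle(
    list(list(box = hyperrectangle(c(0, 0), c(0.25, 0.75)), value = 3)),
    background = 1, box = u2)
  oracle <- function(cell, dist = NULL) orc$exact_expectation(cell)
  dec <- two_value_bisection(oracle, u2, 1, 3,
                             bisection_config(eps = 0.2, delta = 0.01))
  leaves <- c(dec$labels[["1"]], dec$labels[["3"]])
  vols <- vapply(leaves, box_volume, 0)
  expect_lt(abs(sum(vols) - box_volume(u2)), 1e-9)
  for (i in seq_along(leaves)) for (j in seq_len(i - 1L)) {
    expect_equal(pssreg:::box_overlap_volume(leaves[[i]], leaves[[j]]), 0)
  }
})

test_that("constant oracle labels the whole box with one call", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  oracle <- function(cell, dist = NULL) 1
  dec <- two_value_bisection(oracle, u2, 1, 3, bisection_config())
  expect_equal(dec$oracle_calls, 1L)
  expect_length(dec$labels[["1"]], 1L)
})

test_that("worst-case oracle-call count hits the complete-tree bound", {
  # an oracle stuck at the midpoint value forces a complete tree: over a box
  # with all normalized edges equal and eps letting each axis split m times,
  # the number of expectations is exactly sum_{i=0}^{m r} 2^i
  mid_oracle <- function(cell, dist = NULL) 2
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  dec <- two_value_bisection(mid_oracle, u2, 1, 3,
                             bisection_config(eps = 0.5, delta = 0.1))
  expect_equal(dec$oracle_calls, sum(2^(0:2)))  # m = 1, r = 2: 7 calls
  dec2 <- two_value_bisection(mid_oracle, u2, 1, 3,
                              bisection_config(eps = 0.25, delta = 0.1))
  expect_equal(dec2$oracle_calls, sum(2^(0:4)))  # m = 2, r = 2: 31 calls
  u3 <- hyperrectangle(c(0, 0, 0), c(1, 1, 1))
  dec3 <- two_value_bisection(mid_oracle, u3, 1, 3,
                              bisection_config(eps = 0.5, delta = 0.1))
  expect_equal(dec3$oracle_calls, sum(2^(0:3)))  # m = 1, r = 3: 15 calls
})

test_that("uniform expectation decomposes over level-set volumes", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  cells <- list(list(box = hyperrectangle(c(0, 0), c(0.3, 0.6)), value = 3),
                list(box = hyperrectangle(c(0.5, 0.2), c(0.9, 1)), value = 5))
  orc <- synthetic_region_oracle(cells, background = 1, box = u2)
  set.seed(51)
  for (i in 1:10) {
    lo <- runif(2, 0, 0.5); hi <- lo + runif(2, 0.1, 0.5)
    sb <- hyperrectangle(lo, hi)
    # E[g | U(sb)] = sum_i n_i * Volbar(sb ∩ L_{n_i})
    manual <- 0
    covered <- 0
    for (cl in cells) {
      frac <- pssreg:::box_overlap_volume(sb, cl$box) / box_volume(sb)
      manual <- manual + cl$value * frac
      covered <- covered + frac
    }
    manual <- manual + 1 * (1 - covered)
    expect_equal(orc$exact_expectation(sb), manual, tolerance = 1e-12)
  }
})

test_that("two-step bisection splits mixed cells that fool the uniform mean", {
  # cell half-valued 1 / half-valued 5 with admissible counts {1,3,5}: the
  # uniform expectation is exactly 3, but any off-centre distribution sees
  # through it
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  left <- hyperrectangle(c(0, 0), c(0.5, 1))
  orc <- synthetic_region_oracle(list(list(box = left, value = 1)),
                                 background = 5, box = u2)
  oracle <- function(cell, dist = NULL) {
    if (is.null(dist)) orc$exact_expectation(cell)
    else exact_tn_expectation(orc, dist)
  }
  expect_equal(oracle(u2), 3)  # the trap: mean hits an admissible value
  dec <- two_step_bisection(oracle, u2, c(1, 3, 5),
                            bisection_config(eps = 0.5, delta = 0.05, seed = 6),
                            second_dist = truncated_normal_preset(c(0.3, 0.5), 0.05))
  # the box must NOT be labeled L_3; after one split both halves are pure
  expect_length(dec$labels[["3"]], 0L)
  expect_length(dec$labels[["1"]], 1L)
  expect_length(dec$labels[["5"]], 1L)
  expect_equal(dec$labels[["1"]][[1]]$upper, c(0.5, 1))

  # a pure cell is confirmed by the second distribution and labeled at once
  pure <- synthetic_region_oracle(list(), background = 3, box = u2)
  oracle_p <- function(cell, dist = NULL) {
    if (is.null(dist)) pure$exact_expectation(cell)
    else exact_tn_expectation(pure, dist)
  }
  dec2 <- two_step_bisection(oracle_p, u2, c(1, 3, 5),
                             bisection_config(eps = 0.5, delta = 0.05, seed = 7))
  expect_length(dec2$labels[["3"]], 1L)
  expect_equal(dec2$oracle_calls, 2L)  # uniform + confirmation
})

test_that("the quintic rectangle with invariant count is labeled directly", {
  qs <- quintic_fixture()
  B1 <- hyperrectangle(c(0.5, 8), c(1, 9))
  oracle <- make_mc_oracle(qs, n_samples = 300, seed = 8)
  dec <- two_step_bisection(oracle, B1, 0:5,
                            bisection_config(eps = 0.5, delta = 0.1, seed = 8))
  expect_length(dec$labels[["2"]], 1L)
  expect_equal(dec$oracle_calls, 2L)
})

test_that("decomposition_to_K selects cells and samples points from them", {
  c1 <- hyperrectangle(c(0, 0), c(0.5, 0.5))
  c2 <- hyperrectangle(c(0.5, 0), c(1, 0.5))
  c3 <- hyperrectangle(c(0, 0.5), c(1, 1))
  dec <- structure(list(box = hyperrectangle(c(0, 0), c(1, 1)),
                        values = c(1, 3),
                        labels = list(`1` = list(c3), `3` = list(c1, c2)),
                        audit = list(), oracle_calls = 0L),
                   class = "labeled_decomposition")
  sel <- decomposition_to_K(dec, 2)
  expect_length(sel, 2L)
  expect_length(decomposition_to_K(dec, 99), 0L)
  pts <- decomposition_to_K(dec, 2, n_points = 140, seed = 9)
  expect_equal(nrow(pts), 140L)
  inside <- apply(pts, 1, function(k)
    box_contains(c1, k) || box_contains(c2, k))
  expect_true(all(inside))
})
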