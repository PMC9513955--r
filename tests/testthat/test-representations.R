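test_that("sampling representation records in-box points with their counts", {
  qs <- quintic_fixture()
  B1 <- hyperrectangle(c(0.5, 8), c(1, 9))
  sr <- build_sampling_representation(qs, B1, 50, seed = 21)
  expect_equal(nrow(sr$points), 50L)
  expect_true(all(box_contains(B1, sr$points)))
  recount <- apply(sr$points, 1, function(k) count_positive_solutions(qs, k))
  expect_equal(sr$counts, as.integer(recount))
  expect_error(build_sampling_representation(qs, B1, 0), ">= 1")
})

test_that("rectangular representation tiles the box and averages per cell", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  const1 <- synthetic_region_oracle(list(), background = 1, box = u2)$system
  rr <- build_rectangular_representation(const1, u2, c(3, 2), 5, seed = 22)
  expect_length(rr$cells, 6L)
  expect_true(all(rr$averages == 1))
  vols <- vapply(rr$cells, box_volume, 0)
  expect_equal(sum(vols), box_volume(u2))
  # row-major over axes in order: the first axis varies fastest
  expect_equal(rr$cells[[1]]$lower, c(0, 0))
  expect_equal(rr$cells[[2]]$lower, c(1 / 3, 0))
  expect_equal(rr$cells[[4]]$lower, c(0, 0.5))
  # a 1x1 division is plain Monte-Carlo expectation with the same seed
  qs <- quintic_fixture()
  B1 <- hyperrectangle(c(0.5, 8), c(1, 9))
  r1 <- build_rectangular_representation(qs, B1, 1, 64, seed = 23)
  e1 <- expected_count(qs, distribution_spec("uniform", B1), 64, seed = 23)
  expect_equal(r1$averages, e1$value)
})

test_that("cell averages converge to the oracle's exact expectations", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  orc <- synthetic_region_oracle(
    list(list(box = hyperrectangle(c(0, 0), c(0.5, 1)), value = 3)),
    background = 1, box = u2)
  rr <- build_rectangular_representation(orc$system, u2, c(4, 2), 200, seed = 24)
  for (i in seq_along(rr$cells)) {
    ex <- orc$exact_expectation(rr$cells[[i]])
    se <- sqrt(ex * 1) / sqrt(200)  # generous: counts are in {1,3}
    expect_lt(abs(rr$averages[i] - ex), 3 * max(se, 1e-12) + 1e-9)
  }
})

test_that("threshold_cells splits the cells into region and complement", {
  u2 <- hyperrectangle(c(0, 0), c(1, 1))
  rr <- structure(list(box = u2,
                       cells = list(hyperrectangle(c(0, 0), c(0.5, 1)),
                                    hyperrectangle(c(0.5, 0), c(0.75, 1)),
                                    hyperrectangle(c(0.75, 0), c(1, 1))),
                       averages = c(1.0, 2.6, 3.0),
                       divisions = c(3L, 1L), samples_per_cell = 1L, seed = NULL),
                  class = "rectangular_representation")
  sel <- threshold_cells(rr, 2)
  expect_length(sel, 2L)
  expect_equal(sel[[1]]$lower, c(0.5, 0))
  expect_length(threshold_cells(rr, 99), 0L)
  # selected and complement cover everything, with no cell in both
  comp <- rr$cells[rr$averages < 2]
  expect_equal(length(sel) + length(comp), length(rr$cells))
})

test_that("representation CSV files round-trip and reject malformed rows", {
  qs <- quintic_fixture()
  B1 <- hyperrectangle(c(0.5, 8), c(1, 9))
  sr <- build_sampling_representation(qs, B1, 20, seed = 25)
  f <- tempfile(fileext = ".csv")
  write_sampling_csv(sr, f)
  sr2 <- read_sampling_csv(f, box = B1)
  expect_equal(sr2$points, sr$points)
  expect_identical(sr2$counts, sr$counts)

  rr <- build_rectangular_representation(qs, B1, 3, 2, seed = 26)
  fr <- tempfile(fileext = ".csv")
  write_rectangular_csv(rr, fr)
  rr2 <- read_rectangular_csv(fr, box = B1)
  expect_equal(rr2$averages, rr$averages)
  for (i in seq_along(rr$cells)) {
    expect_equal(rr2$cells[[i]]$lower, rr$cells[[i]]$lower)
    expect_equal(rr2$cells[[i]]$upper, rr$cells[[i]]$upper)
  }

  # header-only file: empty representation, not an error
  writeLines("k1,k2,count", f)
  empty <- read_sampling_csv(f)
  expect_equal(nrow(empty$points), 0L)

  # a row of width 2r - 1 is an error naming the row
  writeLines(c("a1,a2,b1,b2,average", "0,0,1,1,2", "0,0,1,2"), fr)
  expect_error(read_rectangular_csv(fr), "row")
  unlink(c(f, fr))
})
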