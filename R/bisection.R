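#' Configuration for the bisection searches
#'
#' @param eps Termination threshold on the normalized edge lengths of a cell
#'   (`0 < eps < 1`). By default a cell stops splitting when ALL its edges,
#'   normalized by the corresponding edges of the root box, are `<= eps` —
#'   the convention under which the worst-case oracle-call count of a search
#'   over a box with edge ratio `2^m` is exactly `sum_{i=0}^{m r} 2^i`.
#'   Setting `termination = "min-edge"` stops instead as soon as ANY
#'   normalized edge is `<= eps`.
#' @param delta Closeness tolerance: an estimate within `delta` of an
#'   admissible count is treated as equal to it. The default 0.1 matches
#'   one-decimal reporting of Monte-Carlo expectations; `delta` must stay
#'   below half the smallest gap between admissible values.
#' @param axis_policy `"round-robin"` (axis cycles with recursion depth) or
#'   `"longest-edge"` (split the longest normalized edge).
#' @param n_samples Monte-Carlo draws per oracle call (used by
#'   [make_mc_oracle()]).
#' @param seed Base seed for the oracle's sample streams.
#' @param termination `"max-edge"` (default) or `"min-edge"`, see `eps`.
#' @param randomize_mean In the two-step search, draw the second
#'   distribution's mean uniformly from the middle half of the cell (default)
#'   rather than using the cell midpoint. A randomly chosen distribution
#'   discriminates mixed cells with probability one; a midpoint mean can fail
#'   on cells whose level-set boundary passes through the center.
#' @param second_sigma Optional per-coordinate standard deviation for the
#'   second distribution; default `(b_j - a_j)/2` for the current cell.
#' @return A list of class `bisection_config`.
#' @export
bisection_config <- function(eps = 0.05, delta = 0.1,
                             axis_policy = c("round-robin", "longest-edge"),
                             n_samples = 200L, seed = NULL,
                             termination = c("max-edge", "min-edge"),
                             randomize_mean = TRUE, second_sigma = NULL) {
  stopifnot(eps > 0, eps < 1, delta > 0)
  structure(list(eps = eps, delta = delta,
                 axis_policy = match.arg(axis_policy),
                 n_samples = as.integer(n_samples), seed = seed,
                 termination = match.arg(termination),
                 randomize_mean = isTRUE(randomize_mean),
                 second_sigma = second_sigma),
            class = "bisection_config")
}

#' Monte-Carlo expectation oracle for a parametric system
#'
#' Wraps a system into the oracle signature the bisection searches consume:
#' `oracle(cell, dist = NULL)` returns the estimated expected count over the
#' cell, under the uniform distribution when `dist` is `NULL` and under the
#' supplied [distribution_spec()] otherwise. Each call uses a fresh seed
#' derived deterministically from `seed` and an internal call counter, so a
#' whole search is reproducible.
#'
#' @param system A [parametric_system()].
#' @param n_samples Draws per call.
#' @param seed Base seed (optional).
#' @return A function `(cell, dist = NULL) -> numeric`.
#' @export
make_mc_oracle <- function(system, n_samples = 200L, seed = NULL) {
  counter <- 0L
  function(cell, dist = NULL) {
    counter <<- counter + 1L
    s <- if (is.null(seed)) NULL else (seed + 7919L * counter) %% 2147483647L
    if (is.null(dist)) dist <- distribution_spec("uniform", cell)
    expected_count(system, dist, n_samples, seed = s)$value
  }
}

.norm_edges <- function(cell, root) (cell$upper - cell$lower) / (root$upper - root$lower)

.terminated <- function(cell, root, config) {
  ne <- .norm_edges(cell, root)
  if (config$termination == "max-edge") max(ne) <= config$eps else min(ne) <= config$eps
}

.split_axis <- function(cell, root, depth, config) {
  r <- box_dim(cell)
  if (config$axis_policy == "round-robin") {
    ax <- depth %% r
    if (ax == 0L) ax <- r   # x mod n taken as n at multiples of n
    ax
  } else {
    which.max(.norm_edges(cell, root))
  }
}

.new_decomposition <- function(box, values) {
  structure(list(box = box, values = values,
                 labels = stats::setNames(rep(list(list()), length(values)),
                                          as.character(values)),
                 audit = list(), oracle_calls = 0L),
            class = "labeled_decomposition")
}

#' @export
print.labeled_decomposition <- function(x, ...) {
  cat("<labeled_decomposition>\n")
  for (v in names(x$labels))
    cat(sprintf("  L_%s: %d cells\n", v, length(x$labels[[v]])))
  cat(sprintf("  oracle calls: %d\n", x$oracle_calls))
  invisible(x)
}

#' Two-value bisection search
#'
#' Adaptive decomposition of a box into level-set cells when the solution
#' count takes only two values `n1 < n2` almost everywhere. On each cell the
#' expected count is estimated; a value within `delta` of `n1` (resp. `n2`)
#' means the cell is almost entirely in the corresponding level set and it is
#' labeled; otherwise the cell is split into two equal halves along one axis
#' and the search recurses, until the termination condition on normalized
#' edge lengths assigns the cell to the nearer value.
#'
#' @param oracle Function `(cell, dist = NULL) -> numeric` (see
#'   [make_mc_oracle()]); only the uniform (default) form is used here.
#' @param B Root box.
#' @param n1,n2 The two admissible counts, `n1 < n2`.
#' @param config A [bisection_config()].
#' @return A `labeled_decomposition`: cells per label, and an audit trail of
#'   oracle calls.
#' @export
two_value_bisection <- function(oracle, B, n1, n2, config = bisection_config()) {
  stopifnot(inherits(B, "hyperrectangle"), n1 < n2)
  dec <- .new_decomposition(B, c(n1, n2))
  assign_cell <- function(cell, value)
    dec$labels[[as.character(value)]][[length(dec$labels[[as.character(value)]]) + 1L]] <<- cell
  recurse <- function(cell, depth) {
    E <- oracle(cell)
    dec$oracle_calls <<- dec$oracle_calls + 1L
    dec$audit[[length(dec$audit) + 1L]] <<- list(cell = cell, estimate = E, depth = depth)
    if (abs(E - n1) <= config$delta) { assign_cell(cell, n1); return(invisible()) }
    if (abs(E - n2) <= config$delta) { assign_cell(cell, n2); return(invisible()) }
    if (.terminated(cell, B, config)) {
      assign_cell(cell, if (abs(E - n1) <= abs(E - n2)) n1 else n2)
      return(invisible())
    }
    halves <- box_bisect(cell, .split_axis(cell, B, depth, config))
    recurse(halves[[1L]], depth + 1L)
    recurse(halves[[2L]], depth + 1L)
  }
  recurse(B, 1L)
  dec
}

# build the second (non-uniform) distribution for a cell
.second_distribution <- function(cell, config) {
  r <- box_dim(cell)
  edges <- cell$upper - cell$lower
  mean <- if (config$randomize_mean) {
    stats::runif(r, cell$lower + edges / 4, cell$upper - edges / 4)
  } else box_midpoint(cell)
  sd <- config$second_sigma %||% (edges / 2)
  distribution_spec("truncated-normal", cell, mean = mean,
                    variance = rep_len(sd, r)^2)
}

#' Fixed truncated-normal confirmation preset
#'
#' Returns a `second_dist` function for [two_step_bisection()] that always
#' uses a truncated normal with the given mean and variance (e.g. the worked
#' quintic confirmation: mean `(2.25, 2.5)`, variance `0.1`), instead of the
#' default randomized-mean distribution.
#'
#' @param mean Mean vector.
#' @param variance Scalar or per-coordinate variance.
#' @return A function `(cell) -> distribution_spec`.
#' @export
truncated_normal_preset <- function(mean, variance) {
  force(mean); force(variance)
  function(cell) distribution_spec("truncated-normal", cell,
                                   mean = mean, variance = variance)
}

#' Two-step bisection search
#'
#' Generalisation of [two_value_bisection()] to counts taking values in a
#' finite set `values`. A uniform expectation close to an admissible value
#' `n_i` is no longer conclusive (a half-and-half mixture of `n_{i-1}` and
#' `n_{i+1}` gives the same mean), so each candidate label is confirmed by a
#' second estimate under a non-uniform distribution on the cell — a truncated
#' normal whose mean, by default, is drawn at random from the middle half of
#' the cell. For a cell almost entirely inside one level set every
#' distribution yields the same expectation; for a mixed cell a randomly
#' chosen distribution yields a different value with probability one, and the
#' cell is split.
#'
#' @param oracle Function `(cell, dist = NULL) -> numeric`; called with a
#'   [distribution_spec()] for the confirmation step.
#' @param B Root box.
#' @param values Sorted vector of admissible counts (length `>= 2`).
#' @param config A [bisection_config()]; `config$seed` drives the random
#'   means of the confirmation distributions.
#' @param second_dist Optional function `(cell) -> distribution_spec`
#'   overriding the default confirmation distribution (e.g. a fixed preset).
#' @return A `labeled_decomposition`.
#' @export
two_step_bisection <- function(oracle, B, values, config = bisection_config(),
                               second_dist = NULL) {
  stopifnot(inherits(B, "hyperrectangle"), length(values) >= 2L)
  values <- sort(unique(values))
  dec <- .new_decomposition(B, values)
  assign_cell <- function(cell, value)
    dec$labels[[as.character(value)]][[length(dec$labels[[as.character(value)]]) + 1L]] <<- cell
  mkdist <- second_dist %||% function(cell) .second_distribution(cell, config)
  recurse <- function(cell, depth) {
    E <- oracle(cell)
    dec$oracle_calls <<- dec$oracle_calls + 1L
    rec <- list(cell = cell, estimate = E, depth = depth)
    i <- which(abs(E - values) <= config$delta)
    confirmed <- FALSE
    if (length(i) == 1L) {
      q <- mkdist(cell)
      E2 <- oracle(cell, q)
      dec$oracle_calls <<- dec$oracle_calls + 1L
      rec$second_estimate <- E2
      confirmed <- abs(E2 - values[i]) <= config$delta
    }
    dec$audit[[length(dec$audit) + 1L]] <<- rec
    if (confirmed) { assign_cell(cell, values[i]); return(invisible()) }
    if (.terminated(cell, B, config)) {
      assign_cell(cell, values[which.min(abs(E - values))])
      return(invisible())
    }
    halves <- box_bisect(cell, .split_axis(cell, B, depth, config))
    recurse(halves[[1L]], depth + 1L)
    recurse(halves[[2L]], depth + 1L)
  }
  with_seed(config$seed, recurse(B, 1L))
  dec
}

#' Extract the multistationary cells (or points) from a decomposition
#'
#' Collects the cells labeled with counts `>= u` — the `K` handed to
#' [fit_pss_from_rectangles()] — or, when `n_points` is given, a uniform
#' sample of that many points from the union of those cells (probability
#' proportional to cell volume), ready for [fit_pss_from_points()].
#'
#' @param dec A `labeled_decomposition`.
#' @param u Count threshold (default 2).
#' @param n_points Optional number of points to sample from the selected cells.
#' @param seed Optional seed for the point sample.
#' @return List of hyperrectangles, or an `n_points x r` matrix.
#' @export
decomposition_to_K <- function(dec, u = 2, n_points = NULL, seed = NULL) {
  stopifnot(inherits(dec, "labeled_decomposition"))
  sel <- unlist(lapply(names(dec$labels), function(v)
    if (as.numeric(v) >= u) dec$labels[[v]] else list()), recursive = FALSE)
  if (is.null(n_points)) return(sel)
  if (!length(sel)) stop("no cells with label >= u to sample from")
  vols <- vapply(sel, box_volume, 0)
  with_seed(seed, {
    pick <- sample.int(length(sel), n_points, replace = TRUE, prob = vols)
    t(vapply(pick, function(i) {
      cl <- sel[[i]]
      stats::runif(box_dim(cl), cl$lower, cl$upper)
    }, numeric(box_dim(sel[[1L]]))))
  })
}
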