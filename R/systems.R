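# run code with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parametric systems
#'
#' The contract every analysis in the package runs against: a parameter
#' dimension `r`, a domain box, and a counter mapping a parameter point `k` to
#' the number of distinct positive solutions of the system at `k` (the value
#' of the solution-count map at `u = 0`). The multistationarity region is the
#' set of `k` where this count is at least 2.
#'
#' @param r Parameter dimension.
#' @param count Function of one argument (numeric vector of length `r`)
#'   returning a nonnegative integer count. It must signal an error on
#'   failure, never silently return 0.
#' @param domain A `hyperrectangle`; parameter points are validated against it.
#' @param value_set Optional integer vector: the counts the system is known to
#'   attain. When given, counts outside it raise an error.
#' @param name Optional label used in printing.
#' @return An object of class `parametric_system`.
#' @seealso [quintic_fixture()], [ssystem_fixture()], [lacitetr_fixture()],
#'   [autoreg_fixture()], [synthetic_region_oracle()]
#' @export
parametric_system <- function(r, count, domain, value_set = NULL, name = "user") {
  r <- as.integer(r)
  stopifnot(r >= 1L, is.function(count), inherits(domain, "hyperrectangle"))
  if (box_dim(domain) != r) stop("domain dimension != r")
  if (!is.null(value_set)) value_set <- sort(unique(as.integer(value_set)))
  structure(list(r = r, count = count, domain = domain,
                 value_set = value_set, name = name),
            class = "parametric_system")
}

#' @export
print.parametric_system <- function(x, ...) {
  cat(sprintf("<parametric_system '%s' r=%d>\n", x$name, x$r))
  print(x$domain)
  if (!is.null(x$value_set))
    cat("  attainable counts:", paste(x$value_set, collapse = ", "), "\n")
  invisible(x)
}

#' Count positive solutions at a parameter point
#'
#' Delegates to the system's counter after validating that `k` lies in the
#' declared domain box. Counter failures propagate as errors carrying the
#' offending point.
#'
#' @param system A [parametric_system()].
#' @param k Numeric parameter vector.
#' @return Nonnegative integer count.
#' @export
count_positive_solutions <- function(system, k) {
  if (length(k) != system$r) stop("dimension mismatch")
  if (!box_contains(system$domain, k))
    stop(sprintf("parameter point (%s) outside the system domain box",
                 paste(format(k), collapse = ", ")))
  n <- tryCatch(system$count(k), error = function(e)
    stop(sprintf("solution counter failed at k=(%s): %s",
                 paste(format(k), collapse = ", "), conditionMessage(e)),
         call. = FALSE))
  n <- as.integer(n)
  if (is.na(n) || n < 0L)
    stop("counter returned an invalid value (must be a nonnegative integer)")
  if (!is.null(system$value_set) && !(n %in% system$value_set))
    stop(sprintf("counter returned %d at k=(%s), outside the declared value set",
                 n, paste(format(k), collapse = ", ")))
  n
}

#' Sampling distributions on a box
#'
#' Two families are supported: the uniform distribution on a box, and the
#' truncated normal on a box in which coordinates are independent normals
#' `N(mean_j, sd_j^2)` conditioned to `[lower_j, upper_j]`. Truncated-normal
#' draws use the per-coordinate inverse CDF, so every sample is inside the box
#' by construction (no rejection loops).
#'
#' @param kind `"uniform"` or `"truncated-normal"`.
#' @param box A `hyperrectangle`.
#' @param mean Numeric vector (truncated normal only); defaults to the box
#'   midpoint.
#' @param variance Positive scalar shared by all coordinates, or a vector of
#'   per-coordinate variances (truncated normal only).
#' @return An object of class `distribution_spec`.
#' @examples
#' B2 <- hyperrectangle(c(2, 2), c(2.5, 3))
#' distribution_spec("truncated-normal", B2, mean = c(2.25, 2.5), variance = 0.1)
#' @export
distribution_spec <- function(kind = c("uniform", "truncated-normal"), box,
                              mean = NULL, variance = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(box, "hyperrectangle"))
  r <- box_dim(box)
  if (kind == "truncated-normal") {
    if (is.null(mean)) mean <- box_midpoint(box)
    if (is.null(variance)) stop("truncated-normal requires a variance")
    if (length(mean) != r) stop("mean dimension mismatch")
    variance <- rep_len(as.numeric(variance), r)
    if (any(variance <= 0)) stop("variance must be positive")
  } else {
    mean <- NULL; variance <- NULL
  }
  structure(list(kind = kind, box = box, mean = mean, variance = variance),
            class = "distribution_spec")
}

#' @rdname distribution_spec
#' @param dist A `distribution_spec`.
#' @param n Number of draws.
#' @param seed Optional integer seed; fixed seed gives identical samples.
#' @return `sample_distribution`: an `n x r` matrix of points inside the box.
#' @export
sample_distribution <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "distribution_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  box <- dist$box; r <- box_dim(box)
  with_seed(seed, {
    if (dist$kind == "uniform") {
      matrix(stats::runif(n * r, rep(box$lower, each = n), rep(box$upper, each = n)),
             n, r)
    } else {
      sd <- sqrt(dist$variance)
      out <- matrix(0, n, r)
      for (j in seq_len(r)) {
        plo <- stats::pnorm(box$lower[j], dist$mean[j], sd[j])
        phi <- stats::pnorm(box$upper[j], dist$mean[j], sd[j])
        if (phi - plo < .Machine$double.xmin)
          stop("truncated normal has numerically zero mass on the box")
        u <- stats::runif(n, plo, phi)
        out[, j] <- pmin(pmax(stats::qnorm(u, dist$mean[j], sd[j]),
                              box$lower[j]), box$upper[j])
      }
      out
    }
  })
}

#' Monte-Carlo expected solution count
#'
#' Estimates `E[count(k)]` for `k` drawn from `dist` by plain Monte Carlo:
#' the sample mean of the positive-solution count over `n_samples` draws,
#' with its standard error. This is the expectation oracle the bisection
#' searches consume.
#'
#' @param system A [parametric_system()].
#' @param dist A [distribution_spec()] whose box lies inside the system domain.
#' @param n_samples Number of draws (`>= 1`).
#' @param seed Optional integer seed (recorded in the result).
#' @return An object of class `expectation_estimate` with fields `value`,
#'   `standard_error`, `n_samples`, `seed`.
#' @examples
#' qs <- quintic_fixture()
#' B1 <- hyperrectangle(c(0.5, 8), c(1, 9))
#' expected_count(qs, distribution_spec("uniform", B1), 500, seed = 1)
#' @export
expected_count <- function(system, dist, n_samples, seed = NULL) {
  stopifnot(inherits(system, "parametric_system"),
            inherits(dist, "distribution_spec"))
  if (!box_is_subset(dist$box, system$domain))
    stop("distribution box is not inside the system domain")
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) stop("n_samples must be >= 1")
  pts <- sample_distribution(dist, n_samples, seed)
  counts <- apply(pts, 1L, function(k) count_positive_solutions(system, k))
  se <- if (n_samples > 1L) stats::sd(counts) / sqrt(n_samples) else 0
  structure(list(value = mean(counts), standard_error = se,
                 n_samples = n_samples, seed = seed, counts = as.integer(counts)),
            class = "expectation_estimate")
}

#' @export
print.expectation_estimate <- function(x, ...) {
  cat(sprintf("expected count %.4f (SE %.4f, n=%d%s)\n", x$value,
              x$standard_error, x$n_samples,
              if (!is.null(x$seed)) paste0(", seed=", x$seed) else ""))
  invisible(x)
}
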