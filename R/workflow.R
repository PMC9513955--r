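#' Run configuration for the end-to-end workflow
#'
#' Bundles everything a full sample/bisect -> threshold -> fit -> verify run
#' needs, so that a run is reproducible from its configuration and seeds
#' alone.
#'
#' @param system A [parametric_system()] or the name of a built-in fixture
#'   (see [fixture_by_name()]).
#' @param box Parameter box to analyse (defaults to the system's domain).
#' @param method `"sampling"` (uniform points), `"rectangular"` (equal grid),
#'   `"two-value"` or `"two-step"` (bisection searches).
#' @param degree Even degree of the superlevel-set fit.
#' @param n Points for the sampling method.
#' @param divisions,samples_per_cell Grid parameters for the rectangular
#'   method.
#' @param values Admissible counts for the bisection methods.
#' @param threshold Count threshold defining the region of interest
#'   (default 2: multistationarity).
#' @param fit_from For bisection/rectangular methods, fit from the selected
#'   `"rectangles"` or from `"points"` sampled out of them.
#' @param n_fit_points Number of points when `fit_from = "points"`.
#' @param bisection A [bisection_config()].
#' @param options A [pss_options()].
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Optional directory: representation CSVs, the polynomial
#'   JSON, and a JSON fit report are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(system, box = NULL, method = c("sampling", "rectangular",
                                                      "two-value", "two-step"),
                       degree = 2L, n = 1000L, divisions = 10L,
                       samples_per_cell = 10L, values = NULL, threshold = 2,
                       fit_from = c("rectangles", "points"),
                       n_fit_points = NULL, bisection = bisection_config(),
                       options = pss_options(), seed = 1L, out_dir = NULL) {
  if (is.character(system)) system <- fixture_by_name(system)
  stopifnot(inherits(system, "parametric_system"))
  if (is.null(box)) box <- system$domain
  if (!inherits(box, "hyperrectangle")) stop("config needs a box")
  method <- match.arg(method)
  fit_from <- match.arg(fit_from)
  if (method == "sampling") fit_from <- "points"
  structure(list(system = system, box = box, method = method,
                 degree = as.integer(degree), n = as.integer(n),
                 divisions = divisions, samples_per_cell = samples_per_cell,
                 values = values, threshold = threshold, fit_from = fit_from,
                 n_fit_points = n_fit_points, bisection = bisection,
                 options = options, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' End-to-end workflow
#'
#' Chains the package stages: build a representation of the solution-count
#' map (sampling, rectangular grid, or one of the bisection searches), select
#' the region where the count is at least `threshold`, fit the polynomial
#' superlevel set, and verify the fit. Each stage logs its seed and status;
#' any stage error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return A list of class `pss_run` with the representation, the selected
#'   `K`, the `pss_representation` fit, the verification report, the log, and
#'   (when `out_dir` is set) the paths of the written artifacts.
#' @examples
#' \donttest{
#' cfg <- run_config("quintic", box = hyperrectangle(c(0.5, 8), c(1, 9)),
#'                   method = "sampling", n = 200, degree = 2, seed = 7)
#' run <- workflow_end_to_end(cfg)
#' run$verification$ok
#' }
#' @export
workflow_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  seed_rep <- config$seed
  seed_fitpts <- config$seed + 1000L
  representation <- NULL; dec <- NULL

  if (config$method == "sampling") {
    representation <- stage("representation",
      build_sampling_representation(config$system, config$box, config$n, seed_rep))
    note("representation", type = "sampling", n = config$n, seed = seed_rep)
    K <- representation$points[representation$counts >= config$threshold, , drop = FALSE]
    if (!nrow(K)) stop("stage 'threshold' failed: no multistationary points found")
    note("threshold", kept = nrow(K), u = config$threshold)
    fit <- stage("fit", fit_pss_from_points(config$box, K, config$degree,
                                            options = config$options))
  } else if (config$method == "rectangular") {
    representation <- stage("representation",
      build_rectangular_representation(config$system, config$box,
                                       config$divisions, config$samples_per_cell,
                                       seed_rep))
    note("representation", type = "rectangular", seed = seed_rep)
    K <- threshold_cells(representation, config$threshold)
    if (!length(K)) stop("stage 'threshold' failed: no cells above threshold")
    note("threshold", kept = length(K), u = config$threshold)
    fit <- .fit_from_K(config, K)
  } else {
    cfgb <- config$bisection
    if (is.null(cfgb$seed)) cfgb$seed <- seed_rep
    oracle <- make_mc_oracle(config$system, cfgb$n_samples, seed = cfgb$seed)
    values <- config$values %||% config$system$value_set
    if (is.null(values) || length(values) < 2L)
      stop("stage 'bisect' failed: admissible values are required")
    dec <- stage("bisect", if (config$method == "two-value") {
      two_value_bisection(oracle, config$box, min(values), max(values), cfgb)
    } else {
      two_step_bisection(oracle, config$box, values, cfgb)
    })
    note("bisect", oracle_calls = dec$oracle_calls, seed = cfgb$seed)
    K <- decomposition_to_K(dec, config$threshold)
    if (!length(K)) stop("stage 'threshold' failed: no cells labeled >= threshold")
    note("threshold", kept = length(K), u = config$threshold)
    fit <- .fit_from_K(config, K, seed_fitpts)
  }
  note("fit", status = fit$solver_status, objective = fit$objective_value)
  Kverify <- if (is.matrix(K)) K else K
  verification <- stage("verify",
    verify_fit(fit, config$box, Kverify, feas_tol = config$options$feas_tol))
  note("verify", ok = verification$ok,
       max_violation_B = verification$max_violation_B,
       max_violation_K = verification$max_violation_K)

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list()
    if (inherits(representation, "sampling_representation")) {
      paths$representation <- file.path(config$out_dir, "sampling.csv")
      write_sampling_csv(representation, paths$representation)
    } else if (inherits(representation, "rectangular_representation")) {
      paths$representation <- file.path(config$out_dir, "rectangular.csv")
      write_rectangular_csv(representation, paths$representation)
    }
    paths$polynomial <- file.path(config$out_dir, "polynomial.json")
    write_polynomial_json(fit$polynomial, paths$polynomial)
    paths$report <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(list(
      objective = fit$objective_value, solver_status = fit$solver_status,
      degree = config$degree, threshold = config$threshold,
      seed = config$seed, verification = verification[c("max_violation_B",
                                                        "max_violation_K", "ok")],
      log = log), paths$report, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  structure(list(config = config, representation = representation,
                 decomposition = dec, K = K, fit = fit,
                 verification = verification, log = log, paths = paths),
            class = "pss_run")
}

.fit_from_K <- function(config, K, seed_pts = NULL) {
  if (config$fit_from == "rectangles") {
    fit_pss_from_rectangles(config$box, K, config$degree, config$options)
  } else {
    npts <- config$n_fit_points %||% (50L * length(K))
    pts <- if (is.matrix(K)) K else {
      dec_like <- structure(list(labels = stats::setNames(list(K), "999"),
                                 box = config$box),
                            class = "labeled_decomposition")
      decomposition_to_K(dec_like, u = 0, n_points = npts, seed = seed_pts)
    }
    fit_pss_from_points(config$box, pts, config$degree, options = config$options)
  }
}

#' @export
print.pss_run <- function(x, ...) {
  cat("<pss_run>\n  method:", x$config$method, " degree:", x$config$degree, "\n")
  cat("  fit status:", x$fit$solver_status,
      " objective:", format(x$fit$objective_value), "\n")
  cat("  verification ok:", x$verification$ok, "\n")
  invisible(x)
}
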