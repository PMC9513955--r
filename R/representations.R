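#' Sampling representation of the solution-count map
#'
#' Draws `n` points uniformly from `box`, counts the positive solutions of the
#' system at each, and stores points and counts together. Thresholding the
#' counts at 2 gives the classic scatter picture of the multistationarity
#' region; the point set also feeds the point-constrained superlevel-set fit.
#'
#' @param system A [parametric_system()].
#' @param box A `hyperrectangle` inside the system domain.
#' @param n Number of samples (`>= 1`).
#' @param seed Optional integer seed.
#' @return An object of class `sampling_representation` with fields `box`,
#'   `points` (`n x r` matrix), `counts`, `seed`.
#' @export
build_sampling_representation <- function(system, box, n, seed = NULL) {
  stopifnot(inherits(system, "parametric_system"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  if (!box_is_subset(box, system$domain)) stop("box not inside system domain")
  pts <- sample_distribution(distribution_spec("uniform", box), n, seed)
  counts <- apply(pts, 1L, function(k) count_positive_solutions(system, k))
  structure(list(box = box, points = pts, counts = as.integer(counts),
                 seed = seed),
            class = "sampling_representation")
}

#' @export
print.sampling_representation <- function(x, ...) {
  cat(sprintf("<sampling_representation: %d points in r=%d>\n",
              nrow(x$points), ncol(x$points)))
  print(table(count = x$counts))
  invisible(x)
}

#' Rectangular representation of the solution-count map
#'
#' Divides `box` into an equal grid (`divisions_per_axis[j]` parts along axis
#' `j`) and assigns to each cell the average positive-solution count over
#' `samples_per_cell` uniform draws from that cell. Cells are ordered
#' row-major over axes in order (the first axis varies fastest), so cell
#' counts are reproducible cell-for-cell under a fixed seed.
#'
#' @param system A [parametric_system()].
#' @param box A `hyperrectangle` inside the system domain.
#' @param divisions_per_axis Integer (recycled) or vector of per-axis division
#'   counts.
#' @param samples_per_cell Uniform draws per cell (`>= 1`).
#' @param seed Optional integer seed.
#' @return An object of class `rectangular_representation` with fields `box`,
#'   `cells` (list of hyperrectangles), `averages`, `samples_per_cell`, `seed`.
#' @export
build_rectangular_representation <- function(system, box, divisions_per_axis,
                                             samples_per_cell, seed = NULL) {
  stopifnot(inherits(system, "parametric_system"))
  r <- box_dim(box)
  div <- rep_len(as.integer(divisions_per_axis), r)
  if (any(is.na(div)) || any(div < 1L)) stop("divisions must be >= 1")
  samples_per_cell <- as.integer(samples_per_cell)
  if (is.na(samples_per_cell) || samples_per_cell < 1L)
    stop("samples_per_cell must be >= 1")
  if (!box_is_subset(box, system$domain)) stop("box not inside system domain")
  edges <- lapply(seq_len(r), function(j)
    seq(box$lower[j], box$upper[j], length.out = div[j] + 1L))
  grid <- as.matrix(expand.grid(lapply(div, seq_len)))  # first axis fastest
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    lo <- vapply(seq_len(r), function(j) edges[[j]][grid[i, j]], 0)
    hi <- vapply(seq_len(r), function(j) edges[[j]][grid[i, j] + 1L], 0)
    hyperrectangle(lo, hi)
  })
  averages <- with_seed(seed, vapply(cells, function(cell) {
    pts <- sample_distribution(distribution_spec("uniform", cell),
                               samples_per_cell, seed = NULL)
    mean(apply(pts, 1L, function(k) count_positive_solutions(system, k)))
  }, 0))
  structure(list(box = box, cells = cells, averages = averages,
                 divisions = div, samples_per_cell = samples_per_cell,
                 seed = seed),
            class = "rectangular_representation")
}

#' @export
print.rectangular_representation <- function(x, ...) {
  cat(sprintf("<rectangular_representation: %d cells (%s), %d samples/cell>\n",
              length(x$cells), paste(x$divisions, collapse = "x"),
              x$samples_per_cell))
  cat("  average count range:", paste(format(range(x$averages)), collapse = " .. "), "\n")
  invisible(x)
}

#' Select the cells above a count threshold
#'
#' Returns the cells whose average solution count is at least `u`, in input
#' order. With the default `u = 2` this is the rectangular approximation `K`
#' of the multistationarity region that the superlevel-set fit consumes.
#'
#' @param rep A `rectangular_representation`.
#' @param u Threshold (default 2).
#' @return List of hyperrectangles (possibly empty).
#' @export
threshold_cells <- function(rep, u = 2) {
  stopifnot(inherits(rep, "rectangular_representation"))
  rep$cells[rep$averages >= u]
}

#' Representation CSV files
#'
#' Sampling representations are stored as `k_1, ..., k_r, count` rows;
#' rectangular representations as `a_1, ..., a_r, b_1, ..., b_r, average`
#' rows (cell lower corner, then upper corner). Both carry a single header
#' line; a header-only file reads back as an empty representation. Malformed
#' rows raise an error naming the row.
#'
#' @param rep The representation to write.
#' @param path File path.
#' @name representation_csv
#' @export
write_sampling_csv <- function(rep, path) {
  stopifnot(inherits(rep, "sampling_representation"))
  r <- ncol(rep$points)
  df <- as.data.frame(rep$points)
  names(df) <- paste0("k", seq_len(r))
  df$count <- rep$counts
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname representation_csv
#' @param box Optional box override; by default the bounding information must
#'   be supplied by the caller when reading (the CSV stores only rows).
#' @export
read_sampling_csv <- function(path, box = NULL) {
  df <- utils::read.csv(path)
  ncol_exp <- ncol(df)
  if (ncol_exp < 2L) stop("sampling CSV needs at least one coordinate and a count column")
  r <- ncol_exp - 1L
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) stop("malformed row ", bad[1L], " in ", path)
  pts <- as.matrix(df[, seq_len(r), drop = FALSE])
  dimnames(pts) <- NULL
  if (is.null(box)) {
    lo <- if (nrow(pts)) apply(pts, 2L, min) else rep(0, r)
    hi <- if (nrow(pts)) apply(pts, 2L, max) else rep(1, r)
    box <- hyperrectangle(lo - 1e-12 - abs(lo) * 1e-12, hi + 1e-12 + abs(hi) * 1e-12)
  }
  structure(list(box = box, points = pts, counts = as.integer(df[[ncol_exp]]),
                 seed = NULL),
            class = "sampling_representation")
}

#' @rdname representation_csv
#' @export
write_rectangular_csv <- function(rep, path) {
  stopifnot(inherits(rep, "rectangular_representation"))
  r <- box_dim(rep$box)
  rows <- t(vapply(rep$cells, function(cl) c(cl$lower, cl$upper), numeric(2 * r)))
  df <- as.data.frame(rows)
  names(df) <- c(paste0("a", seq_len(r)), paste0("b", seq_len(r)))
  df$average <- rep$averages
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname representation_csv
#' @export
read_rectangular_csv <- function(path, box = NULL) {
  df <- utils::read.csv(path)
  nc <- ncol(df)
  if (nc < 3L || (nc - 1L) %% 2L != 0L)
    stop("rectangular CSV needs 2r coordinate columns plus an average column")
  r <- (nc - 1L) %/% 2L
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) stop("malformed row ", bad[1L], " in ", path)
  cells <- lapply(seq_len(nrow(df)), function(i) {
    lo <- as.numeric(df[i, seq_len(r)])
    hi <- as.numeric(df[i, r + seq_len(r)])
    if (any(hi <= lo)) stop("malformed row ", i, " in ", path, " (degenerate cell)")
    hyperrectangle(lo, hi)
  })
  if (is.null(box)) {
    if (length(cells)) {
      lo <- do.call(pmin, lapply(cells, `[[`, "lower"))
      hi <- do.call(pmax, lapply(cells, `[[`, "upper"))
      box <- hyperrectangle(lo, hi)
    } else box <- hyperrectangle(rep(0, r), rep(1, r))
  }
  structure(list(box = box, cells = cells, averages = as.numeric(df[[nc]]),
                 divisions = NA_integer_, samples_per_cell = NA_integer_,
                 seed = NULL),
            class = "rectangular_representation")
}
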