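#' Hyperrectangles (boxes) in parameter space
#'
#' A hyperrectangle `[a, b]` is the Cartesian product of the closed intervals
#' `[a_j, b_j]`. It is the universal region type of the package: the parameter
#' box `B`, the cells of a rectangular representation, and the target
#' rectangles `K_i` of a superlevel-set fit are all hyperrectangles.
#'
#' @param lower Numeric vector of lower bounds.
#' @param upper Numeric vector of upper bounds, same length as `lower`;
#'   `upper[j] > lower[j]` is required for every coordinate (nonzero volume).
#'
#' @return An object of class `hyperrectangle` with fields `lower` and `upper`.
#' @examples
#' B <- hyperrectangle(c(0, 0), c(1, 2))
#' box_volume(B)
#' box_contains(B, c(0.5, 1.5))
#' @export
hyperrectangle <- function(lower, upper) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper))
    stop("lower and upper must have the same length")
  if (!length(lower)) stop("empty hyperrectangle")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(upper <= lower))
    stop("degenerate hyperrectangle: need upper[j] > lower[j] for all j")
  structure(list(lower = lower, upper = upper), class = "hyperrectangle")
}

#' @export
print.hyperrectangle <- function(x, ...) {
  cat(sprintf("<hyperrectangle r=%d>\n", box_dim(x)))
  cat("  [", paste(format(x$lower), collapse = ", "), "] -- [",
      paste(format(x$upper), collapse = ", "), "]\n")
  invisible(x)
}

#' @rdname hyperrectangle
#' @param box A `hyperrectangle`.
#' @export
box_dim <- function(box) length(box$lower)

#' @rdname hyperrectangle
#' @export
box_volume <- function(box) prod(box$upper - box$lower)

#' @rdname hyperrectangle
#' @export
box_midpoint <- function(box) (box$lower + box$upper) / 2

#' Membership and normalized volume
#'
#' Boxes are closed: points on the boundary count as inside (a tolerance
#' `tol` absorbs floating-point noise).
#'
#' @param box,outer `hyperrectangle` objects.
#' @param k Numeric vector (a point) or matrix with one point per row.
#' @param tol Absolute slack applied to both bounds.
#' @return `box_contains`: logical; `box_normalized_volume`: `Vol(box)/Vol(outer)`.
#' @export
box_contains <- function(box, k, tol = 1e-9) {
  if (is.matrix(k)) return(apply(k, 1L, box_contains, box = box, tol = tol))
  if (length(k) != box_dim(box)) stop("dimension mismatch")
  all(k >= box$lower - tol & k <= box$upper + tol)
}

#' @rdname box_contains
#' @export
box_normalized_volume <- function(box, outer) {
  if (box_dim(box) != box_dim(outer)) stop("dimension mismatch")
  box_volume(box) / box_volume(outer)
}

#' @rdname box_contains
#' @export
box_is_subset <- function(box, outer, tol = 1e-9) {
  all(box$lower >= outer$lower - tol) && all(box$upper <= outer$upper + tol)
}

# volume of the intersection of two boxes (0 when disjoint)
box_overlap_volume <- function(a, b) {
  lo <- pmax(a$lower, b$lower); hi <- pmin(a$upper, b$upper)
  if (any(hi <= lo)) return(0)
  prod(hi - lo)
}

#' Split a box into two equal halves along one axis
#'
#' @param box A `hyperrectangle`.
#' @param axis Coordinate index in `1..r`.
#' @return List of two hyperrectangles.
#' @export
box_bisect <- function(box, axis) {
  r <- box_dim(box)
  if (axis < 1 || axis > r) stop("axis out of range")
  mid <- (box$lower[axis] + box$upper[axis]) / 2
  lo1 <- box$lower; hi1 <- box$upper; hi1[axis] <- mid
  lo2 <- box$lower; lo2[axis] <- mid
  list(hyperrectangle(lo1, hi1), hyperrectangle(lo2, box$upper))
}

#' Read and write boxes as JSON
#'
#' The JSON layout is `{"lower": [...], "upper": [...]}`.
#'
#' @param box A `hyperrectangle`.
#' @param path File path.
#' @export
write_box_json <- function(box, path) {
  jsonlite::write_json(list(lower = box$lower, upper = box$upper), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_box_json
#' @export
read_box_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hyperrectangle(x$lower, x$upper)
}

#' Affine change of coordinates
#'
#' The map `x -> scale * x + shift`, applied componentwise. Affine maps carry
#' boxes to boxes and are used to rescale a parameter box to the unit cube
#' before assembling a superlevel-set fit, which conditions the optimization
#' much better when box edges differ by orders of magnitude.
#'
#' @param scale Numeric vector of nonzero scales.
#' @param shift Numeric vector, same length.
#' @return An object of class `affine_map`.
#' @examples
#' m <- box_rescale_map(hyperrectangle(c(0, 0), c(10, 2)))  # unit box -> B
#' affine_apply(m, c(1, 1))
#' @export
affine_map <- function(scale, shift) {
  scale <- as.numeric(scale); shift <- as.numeric(shift)
  if (length(scale) != length(shift)) stop("scale and shift lengths differ")
  if (any(scale == 0) || any(!is.finite(scale)) || any(!is.finite(shift)))
    stop("affine map must be invertible with finite entries")
  structure(list(scale = scale, shift = shift), class = "affine_map")
}

#' @rdname affine_map
#' @param map An `affine_map`.
#' @param x Point (vector) or matrix of points (rows).
#' @export
affine_apply <- function(map, x) {
  if (is.matrix(x)) return(sweep(sweep(x, 2L, map$scale, `*`), 2L, map$shift, `+`))
  map$scale * x + map$shift
}

#' @rdname affine_map
#' @export
affine_invert <- function(map) affine_map(1 / map$scale, -map$shift / map$scale)

#' @rdname affine_map
#' @param box A `hyperrectangle`; `box_rescale_map` returns the map sending the
#'   unit box `[0,1]^r` onto `box`.
#' @export
box_rescale_map <- function(box) {
  affine_map(box$upper - box$lower, box$lower)
}

# image of a box under a (positive- or negative-scale) affine map
box_affine_image <- function(map, box) {
  a <- affine_apply(map, box$lower); b <- affine_apply(map, box$upper)
  hyperrectangle(pmin(a, b), pmax(a, b))
}
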