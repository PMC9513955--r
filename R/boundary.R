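#' Distance from a parameter point to the fitted region boundary
#'
#' The boundary of the superlevel set `U(p)` is the level set
#' `{k : p(k) = 1}`. The distance of a point `k*` (inside or outside `U(p)`)
#' from it is found with Lagrange multipliers: critical points of
#' `F(k, lambda) = |k - k*|^2 + lambda (p(k) - 1)` satisfy
#' `2 (k - k*) + lambda grad p(k) = 0` and `p(k) = 1`. The polynomial
#' critical-point system is solved by a deterministic multi-start Newton
#' scheme (starts on a grid over `B`, analytic gradient and Hessian of `p`),
#' converged solutions are deduplicated and filtered to the box, and the
#' minimiser gives the distance.
#'
#' @param pss A `pss_representation` (or a bare `dense_polynomial`, in which
#'   case the level is 1).
#' @param k_star Parameter point of interest.
#' @param B Box in which critical points are accepted (defaults to the fit's
#'   box).
#' @param starts_per_axis Grid resolution of Newton starts per axis (total
#'   starts capped at 10^4).
#' @param tol Newton convergence tolerance on the residual.
#' @return A list of class `distance_result`: `distance`, `nearest_point`,
#'   `critical_points` (matrix), `in_box` flags, `level_values`.
#' @examples
#' p <- dense_polynomial(2, 2, c(0, 0, 0, 1, 0, 1))  # k1^2 + k2^2
#' pss <- structure(list(polynomial = p, threshold = 1,
#'                       box = hyperrectangle(c(-3, -3), c(3, 3))),
#'                  class = "pss_representation")
#' distance_to_boundary(pss, c(2, 0))$distance  # 1
#' @export
distance_to_boundary <- function(pss, k_star, B = NULL, starts_per_axis = 5L,
                                 tol = 1e-10) {
  if (inherits(pss, "dense_polynomial"))
    pss <- structure(list(polynomial = pss, threshold = 1, box = B),
                     class = "pss_representation")
  stopifnot(inherits(pss, "pss_representation"))
  p <- pss$polynomial
  if (is.null(B)) B <- pss$box
  stopifnot(inherits(B, "hyperrectangle"))
  r <- p$r
  if (length(k_star) != r) stop("dimension mismatch")
  level <- pss$threshold

  grads <- poly_grad(p)
  hess <- lapply(grads, poly_grad)
  grad_at <- function(k) vapply(grads, poly_eval, 0, point = k)
  hess_at <- function(k) {
    H <- matrix(0, r, r)
    for (i in seq_len(r)) for (j in seq_len(r))
      H[i, j] <- poly_eval(hess[[i]][[j]], k)
    .sdp_sym(H)
  }

  # degenerate case: k* already on the level set (within fit tolerance)
  if (abs(poly_eval(p, k_star) - level) <= 1e-8 * (1 + abs(level))) {
    return(structure(list(distance = 0, nearest_point = k_star,
                          critical_points = matrix(k_star, 1L),
                          in_box = TRUE, level_values = level),
                     class = "distance_result"))
  }

  attempt_starts <- unique(c(starts_per_axis, 3L * starts_per_axis))
  sols <- list()
  for (spa in attempt_starts) {
  starts <- .box_grid(B, spa, cap = 1e4)
  for (s in seq_len(nrow(starts))) {
    k <- starts[s, ]
    g <- grad_at(k)
    lam <- if (sum(g^2) > 1e-14) -2 * sum((k - k_star) * g) / sum(g^2) else 0
    ok <- FALSE
    for (iter in 1:60) {
      g <- grad_at(k)
      Fv <- c(2 * (k - k_star) + lam * g, poly_eval(p, k) - level)
      if (sqrt(sum(Fv^2)) < tol) { ok <- TRUE; break }
      J <- rbind(cbind(2 * diag(r) + lam * hess_at(k), g),
                 c(g, 0))
      step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
      if (is.null(step)) break
      # damped update, keep iterates bounded
      if (sqrt(sum(step^2)) > 10 * sqrt(sum((B$upper - B$lower)^2)))
        step <- step * 10 * sqrt(sum((B$upper - B$lower)^2)) / sqrt(sum(step^2))
      k <- k + step[seq_len(r)]
      lam <- lam + step[r + 1L]
    }
    if (ok && all(is.finite(k))) sols[[length(sols) + 1L]] <- k
  }
  # a denser start grid is only needed when nothing inside B converged
  if (length(sols) &&
      any(vapply(sols, function(k) box_contains(B, k), TRUE))) break
  }
  if (!length(sols)) {
    # a flat fit (p within tolerance of the level everywhere near k*) has a
    # vanishing gradient: the point effectively sits on the boundary
    if (abs(poly_eval(p, k_star) - level) <= 1e-6 * (1 + abs(level)))
      return(structure(list(distance = 0, nearest_point = k_star,
                            critical_points = matrix(k_star, 1L),
                            in_box = TRUE, level_values = poly_eval(p, k_star)),
                       class = "distance_result"))
    stop("boundary not found in box: no critical point of the Lagrangian converged")
  }
  pts <- do.call(rbind, sols)
  # deduplicate at 1e-6 relative scale of the box diagonal
  scale <- sqrt(sum((B$upper - B$lower)^2))
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) if (keep[i] && i < nrow(pts)) {
    for (j in (i + 1L):nrow(pts)) {
      if (keep[j] && sqrt(sum((pts[i, ] - pts[j, ])^2)) < 1e-6 * scale)
        keep[j] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  inb <- apply(pts, 1L, box_contains, box = B)
  if (!any(inb))
    stop("boundary not found in box: all critical points lie outside B")
  dists <- sqrt(rowSums((pts - matrix(k_star, nrow(pts), r, byrow = TRUE))^2))
  cand <- which(inb)
  best <- cand[which.min(dists[cand])]
  structure(list(distance = dists[best],
                 nearest_point = unname(pts[best, ]),
                 critical_points = unname(pts), in_box = unname(inb),
                 level_values = unname(poly_eval(p, pts))),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result: distance %.8g>\n", x$distance))
  cat("  nearest point: (", paste(format(x$nearest_point), collapse = ", "), ")\n")
  cat(sprintf("  critical points found: %d (%d in box)\n",
              nrow(x$critical_points), sum(x$in_box)))
  invisible(x)
}
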