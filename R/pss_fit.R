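#' Options for superlevel-set fits
#'
#' @param rescale Fit in coordinates rescaled to the unit box and compose the
#'   polynomial back (default `TRUE`). Parameter boxes whose edges differ by
#'   orders of magnitude condition the conic program very poorly otherwise.
#' @param feas_tol Feasibility tolerance used by [verify_fit()] and the
#'   post-fit containment checks.
#' @param solver_tol Relative gap / residual target of the interior-point
#'   solver.
#' @param max_iter Interior-point iteration cap.
#' @param n_pos Number of sampled positivity points in
#'   `positivity = "sampled"` mode; default `max(1000, 100 * r)`.
#' @param seed Seed for the sampled positivity points.
#' @return A list of class `pss_options`.
#' @export
pss_options <- function(rescale = TRUE, feas_tol = 1e-6, solver_tol = 1e-9,
                        max_iter = 100L, n_pos = NULL, seed = 1L) {
  structure(list(rescale = isTRUE(rescale), feas_tol = feas_tol,
                 solver_tol = solver_tol, max_iter = as.integer(max_iter),
                 n_pos = n_pos, seed = seed),
            class = "pss_options")
}

# Coefficient-extraction matrices of one sum-of-squares certificate
#
#   q(x) = m_h(x)' Q0 m_h(x) + sum_j s_j(x) g_j(x),  s_j = m_{h-1}' Qj m_{h-1}
#
# over the box `region` with g_j(x) = (x_j - a_j)(b_j - x_j). Returns, for
# each monomial alpha of the degree-d basis, the matrices E st
# coeff_alpha(q) = sum_blocks <E_alpha^blk, Q_blk>.
.sos_certificate <- function(region, r, d, basis_d, idx_d) {
  h <- d %/% 2L
  basis_h <- basis_enumerate(r, h)
  nh <- nrow(basis_h)
  basis_g <- if (h >= 1L) basis_enumerate(r, h - 1L) else NULL
  ng <- if (is.null(basis_g)) 0L else nrow(basis_g)
  N <- nrow(basis_d)
  E <- lapply(seq_len(N), function(t)
    list(Q0 = matrix(0, nh, nh),
         S = if (ng) lapply(seq_len(r), function(j) matrix(0, ng, ng)) else list()))
  for (i in seq_len(nh)) for (j in seq_len(nh)) {
    al <- basis_h[i, ] + basis_h[j, ]
    t <- idx_d[[.basis_key(al)]]
    E[[t]]$Q0[i, j] <- E[[t]]$Q0[i, j] + 1
  }
  if (ng) {
    a <- region$lower; b <- region$upper
    for (l in seq_len(r)) {
      el <- integer(r); el[l] <- 1L
      for (i in seq_len(ng)) for (j in seq_len(ng)) {
        base <- basis_g[i, ] + basis_g[j, ]
        t0 <- idx_d[[.basis_key(base)]]
        t1 <- idx_d[[.basis_key(base + el)]]
        t2 <- idx_d[[.basis_key(base + 2L * el)]]
        E[[t0]]$S[[l]][i, j] <- E[[t0]]$S[[l]][i, j] - a[l] * b[l]
        E[[t1]]$S[[l]][i, j] <- E[[t1]]$S[[l]][i, j] + (a[l] + b[l])
        E[[t2]]$S[[l]][i, j] <- E[[t2]]$S[[l]][i, j] - 1
      }
    }
  }
  list(E = E, nh = nh, ng = ng, basis_h = basis_h, basis_g = basis_g)
}

# evaluate the monomial vector of a basis at a point
.mono_vec <- function(basis, z) apply(basis, 1L, function(a) prod(z^a))

.pss_result <- function(p, B, objective, status, rescaled, info, kind) {
  structure(list(polynomial = p, box = B, threshold = 1,
                 objective_value = objective, solver_status = status,
                 fitted_in_rescaled_coords = rescaled, solver_info = info,
                 kind = kind),
            class = "pss_representation")
}

#' @export
print.pss_representation <- function(x, ...) {
  cat(sprintf("<pss_representation: degree %d in r=%d, threshold %g>\n",
              x$polynomial$d, x$polynomial$r, x$threshold))
  cat(sprintf("  objective (integral of p over B): %.8g\n", x$objective_value))
  cat(sprintf("  solver status: %s (%d iterations)\n", x$solver_status,
              x$solver_info$iterations))
  invisible(x)
}

.check_solver <- function(res) {
  ok <- identical(res$status, "optimal") || startsWith(res$status, "inaccurate")
  if (!ok)
    stop(sprintf("conic solver failed: status '%s' (relgap %.2e, pres %.2e, dres %.2e)",
                 res$status, res$relgap %||% NA, res$pres %||% NA, res$dres %||% NA),
         call. = FALSE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a polynomial superlevel set to a union of rectangles
#'
#' Finds the polynomial `p` of total degree `d` minimising the integral of `p`
#' over the box `B` subject to `p >= 0` on `B` and `p >= 1` on every rectangle
#' `K_i`, so that the superlevel set `U(p) = {k : p(k) >= 1}` approximates the
#' union of the `K_i` from outside. Positivity on each box is enforced by the
#' interval sum-of-squares certificate
#' `q = sigma_0 + sum_j s_j (x_j - a_j)(b_j - x_j)` with `sigma_0` a sum of
#' squares of degree `2h` and `s_j` of degree `2h - 2`, `h = d/2`; the
#' resulting semidefinite program is solved by the package's interior-point
#' method. The minimisation makes `U(p)` shrink onto the target: as `d` grows
#' the spare volume `Vol(U(p) - K)` tends to zero.
#'
#' @param B Parameter box (`hyperrectangle`).
#' @param K Nonempty list of hyperrectangles, each contained in `B`.
#' @param d Even total degree `>= 2`.
#' @param options A [pss_options()] list.
#' @return A `pss_representation` with the polynomial in ORIGINAL coordinates,
#'   the objective `integral of p over B`, and the verbatim solver status.
#' @examples
#' B <- hyperrectangle(-1, 1)
#' fit <- fit_pss_from_rectangles(B, list(hyperrectangle(-0.5, 0.5)), d = 2)
#' fit$objective_value  # 16/9
#' @export
fit_pss_from_rectangles <- function(B, K, d, options = pss_options()) {
  stopifnot(inherits(B, "hyperrectangle"))
  d <- as.integer(d)
  if (d < 2L || d %% 2L != 0L)
    stop("d must be an even integer >= 2 (certificate half-degrees must match)")
  if (!length(K)) stop("empty target set")
  if (inherits(K, "hyperrectangle")) K <- list(K)
  r <- box_dim(B)
  for (Ki in K) {
    if (!inherits(Ki, "hyperrectangle") || box_dim(Ki) != r)
      stop("K must be a list of hyperrectangles of the same dimension as B")
    if (!box_is_subset(Ki, B)) stop("every K_i must be contained in B")
  }
  rescale <- options$rescale
  if (rescale) {
    to_B <- box_rescale_map(B)           # unit -> B
    from_B <- affine_invert(to_B)        # B -> unit
    Bf <- hyperrectangle(rep(0, r), rep(1, r))
    Kf <- lapply(K, function(Ki) box_affine_image(from_B, Ki))
  } else {
    Bf <- B; Kf <- K
  }
  basis_d <- basis_enumerate(r, d)
  idx_d <- .basis_index(basis_d)
  N <- nrow(basis_d)
  certB <- .sos_certificate(Bf, r, d, basis_d, idx_d)
  certK <- lapply(Kf, function(Ki) .sos_certificate(Ki, r, d, basis_d, idx_d))
  nblk_per <- 1L + (if (certB$ng) r else 0L)
  blocks <- c(certB$nh, rep(certB$ng, if (certB$ng) r else 0L))
  for (ck in certK) blocks <- c(blocks, ck$nh, rep(ck$ng, if (ck$ng) r else 0L))
  w <- apply(basis_d, 1L, function(a) monomial_integral(Bf, a))

  put_cert <- function(mats, cert, offset, coef, t) {
    mats[[offset + 1L]] <- coef * cert$E[[t]]$Q0
    if (cert$ng) for (l in seq_len(r))
      mats[[offset + 1L + l]] <- coef * cert$E[[t]]$S[[l]]
    mats
  }
  A <- vector("list", length(K) * N)
  b <- numeric(length(K) * N)
  ci <- 0L
  for (i in seq_along(K)) {
    off_i <- nblk_per * i
    for (t in seq_len(N)) {
      ci <- ci + 1L
      mats <- vector("list", length(blocks))
      mats <- put_cert(mats, certB, 0L, 1, t)
      mats <- put_cert(mats, certK[[i]], off_i, -1, t)
      A[[ci]] <- list(mats = mats, diag = numeric(0))
      b[ci] <- if (t == 1L) 1 else 0
    }
  }
  Cm <- vector("list", length(blocks))
  for (t in seq_len(N)) {
    contrib <- put_cert(vector("list", length(blocks)), certB, 0L, w[t], t)
    for (j in seq_len(nblk_per))
      Cm[[j]] <- (if (is.null(Cm[[j]])) 0 else Cm[[j]]) + contrib[[j]]
  }
  Cc <- list(mats = Cm, diag = numeric(0))
  res <- solve_block_sdp(Cc, A, b, blocks, ndiag = 0L,
                         max_iter = options$max_iter, tol = options$solver_tol)
  .check_solver(res)
  coefs <- vapply(seq_len(N), function(t) {
    s <- sum(certB$E[[t]]$Q0 * res$X[[1L]])
    if (certB$ng) for (l in seq_len(r))
      s <- s + sum(certB$E[[t]]$S[[l]] * res$X[[1L + l]])
    s
  }, 0)
  p_f <- dense_polynomial(r, d, coefs)
  p <- if (rescale) affine_compose(p_f, from_B) else p_f
  .pss_result(p, B, poly_integral(p, B), res$status, rescale,
              list(iterations = res$iterations, relgap = res$relgap,
                   pres = res$pres, dres = res$dres, dobj = res$dobj),
              kind = "rectangles")
}

#' Fit a polynomial superlevel set to a finite point set
#'
#' Same objective as [fit_pss_from_rectangles()], but the target constraint is
#' `p(a_i) >= 1` at each supplied point (a linear constraint per point).
#' Positivity of `p` on `B` is enforced either by the interval sum-of-squares
#' certificate (`positivity = "sos"`, the default) or by sampling `n_pos`
#' uniform points from `B` and requiring `p >= 0` there
#' (`positivity = "sampled"`), which turns the whole fit into a linear
#' program.
#'
#' @param B Parameter box.
#' @param points Numeric matrix (one point per row) or vector (single point),
#'   all inside `B`.
#' @param d Total degree: even `>= 2` for `"sos"`, any `>= 1` for `"sampled"`.
#' @param positivity `"sos"` or `"sampled"`.
#' @param options A [pss_options()]; in sampled mode `n_pos` and `seed` are
#'   recorded in the result.
#' @return A `pss_representation`.
#' @examples
#' B <- hyperrectangle(-1, 1)
#' fit <- fit_pss_from_points(B, matrix(0), d = 2)
#' fit$objective_value  # 4/3, p = 1 - x^2
#' @export
fit_pss_from_points <- function(B, points, d, positivity = c("sos", "sampled"),
                                options = pss_options()) {
  stopifnot(inherits(B, "hyperrectangle"))
  positivity <- match.arg(positivity)
  r <- box_dim(B)
  if (!is.matrix(points)) points <- matrix(points, ncol = r)
  if (!nrow(points)) stop("empty target set")
  if (ncol(points) != r) stop("points must have r columns")
  if (!all(box_contains(B, points))) stop("all points must lie inside B")
  d <- as.integer(d)
  if (positivity == "sos" && (d < 2L || d %% 2L != 0L))
    stop("d must be an even integer >= 2 in sos mode")
  if (positivity == "sampled" && d < 1L) stop("d must be >= 1")

  rescale <- options$rescale
  if (rescale) {
    from_B <- affine_invert(box_rescale_map(B))
    Bf <- hyperrectangle(rep(0, r), rep(1, r))
    pts <- affine_apply(from_B, points)
  } else {
    Bf <- B; pts <- points
  }
  basis_d <- basis_enumerate(r, d)
  idx_d <- .basis_index(basis_d)
  N <- nrow(basis_d)
  w <- apply(basis_d, 1L, function(a) monomial_integral(Bf, a))
  m <- nrow(pts)
  info_extra <- list()

  if (positivity == "sos") {
    certB <- .sos_certificate(Bf, r, d, basis_d, idx_d)
    blocks <- c(certB$nh, rep(certB$ng, if (certB$ng) r else 0L))
    g_of <- function(z) (z - Bf$lower) * (Bf$upper - z)
    A <- vector("list", m); b <- rep(1, m)
    for (t in seq_len(m)) {
      z <- pts[t, ]
      mh <- .mono_vec(certB$basis_h, z)
      mats <- vector("list", length(blocks))
      mats[[1L]] <- tcrossprod(mh)
      if (certB$ng) {
        mg <- .mono_vec(certB$basis_g, z)
        gz <- g_of(z)
        for (l in seq_len(r)) mats[[1L + l]] <- gz[l] * tcrossprod(mg)
      }
      dg <- -1; names(dg) <- as.character(t)
      A[[t]] <- list(mats = mats, diag = dg)
    }
    Cm <- vector("list", length(blocks))
    for (t in seq_len(N)) {
      Cm[[1L]] <- (if (is.null(Cm[[1L]])) 0 else Cm[[1L]]) + w[t] * certB$E[[t]]$Q0
      if (certB$ng) for (l in seq_len(r)) {
        j <- 1L + l
        Cm[[j]] <- (if (is.null(Cm[[j]])) 0 else Cm[[j]]) + w[t] * certB$E[[t]]$S[[l]]
      }
    }
    Cc <- list(mats = Cm, diag = numeric(m))
    res <- solve_block_sdp(Cc, A, b, blocks, ndiag = m,
                           max_iter = options$max_iter, tol = options$solver_tol)
    .check_solver(res)
    coefs <- vapply(seq_len(N), function(t) {
      s <- sum(certB$E[[t]]$Q0 * res$X[[1L]])
      if (certB$ng) for (l in seq_len(r))
        s <- s + sum(certB$E[[t]]$S[[l]] * res$X[[1L + l]])
      s
    }, 0)
  } else {
    n_pos <- options$n_pos %||% max(1000L, 100L * r)
    pos_pts <- sample_distribution(distribution_spec("uniform", Bf), n_pos,
                                   seed = options$seed)
    V1 <- t(apply(pts, 1L, function(z) .mono_vec(basis_d, z)))
    V0 <- t(apply(pos_pts, 1L, function(z) .mono_vec(basis_d, z)))
    # linear program: min w'c  s.t.  p >= 1 at target points, p >= 0 at the
    # sampled positivity points
    res <- solve_lp_ineq(w, rbind(V1, V0), c(rep(1, m), rep(0, n_pos)),
                         max_iter = options$max_iter, tol = options$solver_tol)
    .check_solver(res)
    coefs <- res$c
    info_extra <- list(n_pos = n_pos, positivity_seed = options$seed)
  }
  p_f <- dense_polynomial(r, d, coefs)
  p <- if (rescale) affine_compose(p_f, from_B) else p_f
  .pss_result(p, B, poly_integral(p, B), res$status, rescale,
              c(list(iterations = res$iterations, relgap = res$relgap,
                     pres = res$pres, dres = res$dres, dobj = res$dobj),
                info_extra),
              kind = paste0("points-", positivity))
}

#' Membership test for a fitted superlevel set
#'
#' A point belongs to `U(p)` when `p(k) >= 1` (the set is closed, so exact
#' equality counts as inside). Points outside the fit's box are reported as
#' non-members with a warning, since the fit carries no information there.
#'
#' @param pss A `pss_representation`.
#' @param k Parameter point.
#' @return Logical.
#' @export
pss_member <- function(pss, k) {
  stopifnot(inherits(pss, "pss_representation"))
  if (!box_contains(pss$box, k)) {
    warning("point lies outside the fitted box; reporting FALSE")
    return(FALSE)
  }
  poly_eval(pss$polynomial, k) >= pss$threshold
}

# deterministic grid over a box; total size capped
.box_grid <- function(box, per_axis, cap = 2e5) {
  r <- box_dim(box)
  g <- max(2L, min(as.integer(per_axis), as.integer(floor(cap^(1 / r)))))
  pts <- as.matrix(expand.grid(lapply(seq_len(r), function(j)
    seq(box$lower[j], box$upper[j], length.out = g))))
  dimnames(pts) <- NULL
  pts
}

#' Verify a superlevel-set fit on evaluation grids
#'
#' Checks `p >= 0` on a grid over `B` and `p >= 1` on a grid over each target
#' rectangle, reporting the worst violations. A fit passes when both are above
#' `-feas_tol`.
#'
#' @param pss A `pss_representation`.
#' @param B Box to check nonnegativity on (defaults to the fit's box).
#' @param K List of target hyperrectangles (or a matrix of target points) to
#'   check the `p >= 1` side on; optional.
#' @param grid_per_axis Grid resolution per axis (capped so the total grid
#'   stays bounded in high dimension).
#' @param feas_tol Pass/fail tolerance.
#' @return A list with `max_violation_B`, `max_violation_K`, `ok`.
#' @export
verify_fit <- function(pss, B = pss$box, K = NULL, grid_per_axis = 11L,
                       feas_tol = 1e-6) {
  stopifnot(inherits(pss, "pss_representation"))
  p <- pss$polynomial
  vB <- max(0 - poly_eval(p, .box_grid(B, grid_per_axis)), 0)
  vK <- 0
  if (!is.null(K)) {
    if (is.matrix(K)) {
      vK <- max(pss$threshold - poly_eval(p, K), 0)
    } else {
      if (inherits(K, "hyperrectangle")) K <- list(K)
      for (Ki in K)
        vK <- max(vK, pss$threshold - min(poly_eval(p, .box_grid(Ki, grid_per_axis))))
      vK <- max(vK, 0)
    }
  }
  list(max_violation_B = vB, max_violation_K = vK,
       ok = vB <= feas_tol && vK <= feas_tol, feas_tol = feas_tol)
}

#' Monte-Carlo normalized volume of a superlevel set
#'
#' Estimates `Vol(U(p) ∩ B) / Vol(B)` by uniform sampling.
#'
#' @param pss A `pss_representation`.
#' @param n_mc Number of samples.
#' @param seed Optional seed.
#' @return Numeric estimate with a `standard_error` attribute.
#' @export
superlevel_volume <- function(pss, n_mc = 10000L, seed = NULL) {
  stopifnot(inherits(pss, "pss_representation"))
  pts <- sample_distribution(distribution_spec("uniform", pss$box), n_mc, seed)
  inside <- poly_eval(pss$polynomial, pts) >= pss$threshold
  est <- mean(inside)
  attr(est, "standard_error") <- stats::sd(inside) / sqrt(n_mc)
  est
}
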