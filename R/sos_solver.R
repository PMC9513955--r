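# Internal dense interior-point solver for conic programs in standard primal
# form over a product of small PSD blocks and a nonnegative orthant:
#
#   min <C, X>   s.t.  <A_i, X> = b_i (i = 1..m),   X >= 0 (blockwise)
#
# Infeasible-start primal-dual path following with the HKM direction and a
# Mehrotra predictor-corrector step. All sum-of-squares fitting programs in
# the package reduce to this form with Gram blocks of dimension at most a few
# dozen, for which dense linear algebra on the Schur complement is entirely
# adequate. The nonnegative orthant part holds slack variables (point-mode
# inequality constraints) and linear-programming variables in sampled
# positivity mode.
#
# X, Z: list of symmetric matrices (one per block) + a nonnegative vector.
# A[[i]]: list(mats = list indexed by block (NULL if untouched), diag = named
# numeric sparse vector over the orthant part).

.sdp_sym <- function(M) (M + t(M)) / 2

# Inequality-form LP solver:  min w'c  s.t.  G c >= h  (c free).
# Primal-dual path following with Mehrotra corrector on the slack/multiplier
# pair; the normal equations G' diag(z/s) G are only ncol(G) x ncol(G), which
# keeps sampled-positivity fits with thousands of constraint points cheap.
solve_lp_ineq <- function(w, G, h, max_iter = 100L, tol = 1e-9) {
  n <- ncol(G); m <- nrow(G)
  c_ <- numeric(n); s <- rep(1, m); z <- rep(1, m)
  status <- "max_iterations"; best <- NULL; it_done <- 0L
  nw <- 1 + sqrt(sum(w^2)); nh <- 1 + sqrt(sum(h^2))
  for (it in seq_len(max_iter)) {
    it_done <- it
    Gc <- as.vector(G %*% c_)
    rp <- Gc - s - h                 # primal residual
    rd <- w - as.vector(crossprod(G, z))  # dual residual
    mu <- sum(s * z) / m
    pobj <- sum(w * c_); dobj <- sum(h * z)
    relgap <- abs(pobj - dobj) / (1 + abs(pobj) + abs(dobj))
    pres <- sqrt(sum(rp^2)) / nh; dres <- sqrt(sum(rd^2)) / nw
    merit <- max(relgap, pres, dres)
    if (is.null(best) || merit < best$merit)
      best <- list(c = c_, s = s, z = z, merit = merit, pobj = pobj,
                   relgap = relgap, pres = pres, dres = dres)
    if (merit < tol) { status <- "optimal"; break }
    M <- crossprod(G, G * (z / s))
    Mch <- tryCatch(chol(M + diag(1e-12 * max(diag(M), 1), n)),
                    error = function(e) NULL)
    if (is.null(Mch)) { status <- "numerical_problems"; break }
    solveM <- function(r) backsolve(Mch, forwardsolve(t(Mch), r))
    dir <- function(nu, corr = 0) {
      t1 <- -(z / s) * rp + (nu - s * z - corr) / s
      dc <- solveM(-rd + as.vector(crossprod(G, t1)))
      dz <- t1 - (z / s) * as.vector(G %*% dc)
      ds <- (nu - s * z - corr) / z - (s / z) * dz
      list(dc = dc, ds = ds, dz = dz)
    }
    alen <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) 1 else min(1, 0.98 * min(-v[neg] / dv[neg]))
    }
    aff <- dir(0)
    ap <- alen(s, aff$ds); ad <- alen(z, aff$dz)
    mu_aff <- sum((s + ap * aff$ds) * (z + ad * aff$dz)) / m
    sigma <- min(max((max(mu_aff, 0) / mu)^3, 1e-10), 1)
    stp <- dir(sigma * mu, corr = aff$ds * aff$dz)
    ap <- alen(s, stp$ds); ad <- alen(z, stp$dz)
    if (ap < 1e-12 && ad < 1e-12) { status <- "stalled"; break }
    c_ <- c_ + ap * stp$dc; s <- s + ap * stp$ds; z <- z + ad * stp$dz
  }
  if (status %in% c("max_iterations", "stalled", "numerical_problems") &&
      !is.null(best) && best$merit < 1e-6)
    status <- paste0("inaccurate (", status, ")")
  list(c = best$c, status = status, pobj = best$pobj, relgap = best$relgap,
       pres = best$pres, dres = best$dres, iterations = it_done)
}

# Adaptive front end: aggressive steps first; on partial convergence retry
# with damped steps, which resolves the late-stage Schur ill-conditioning
# seen on higher-degree certificates. Keeps the most accurate iterate.
solve_block_sdp <- function(C, A, b, blocks, ndiag,
                            max_iter = 100L, tol = 1e-9, verbose = FALSE) {
  best <- NULL
  for (sf in c(0.98, 0.9, 0.8)) {
    res <- solve_block_sdp_once(C, A, b, blocks, ndiag, max_iter = max_iter,
                                tol = tol, step_frac = sf, verbose = verbose)
    merit <- res$merit %||% Inf
    if (is.null(best) || merit < best$merit %||% Inf) best <- res
    if (identical(best$status, "optimal") || (best$merit %||% Inf) < 10 * tol)
      break
  }
  best
}

solve_block_sdp_once <- function(C, A, b, blocks, ndiag,
                                 max_iter = 100L, tol = 1e-9, step_frac = 0.98,
                                 verbose = FALSE) {
  m <- length(A); nb <- length(blocks)
  nt <- sum(blocks) + ndiag
  diag_idx <- function(a) as.integer(names(a$diag))

  norm_a <- vapply(A, function(a) {
    s <- 0
    if (nb) for (j in seq_len(nb)) if (!is.null(a$mats[[j]])) s <- s + sum(a$mats[[j]]^2)
    if (length(a$diag)) s <- s + sum(a$diag^2)
    sqrt(s)
  }, 0)
  # normalize each constraint to unit Frobenius norm (conditioning)
  row_scale <- pmax(norm_a, 1e-12)
  for (i in seq_len(m)) {
    a <- A[[i]]
    if (nb) for (j in seq_len(nb)) if (!is.null(a$mats[[j]]))
      a$mats[[j]] <- a$mats[[j]] / row_scale[i]
    if (length(a$diag)) a$diag <- a$diag / row_scale[i]
    A[[i]] <- a
  }
  b <- b / row_scale
  norm_a <- norm_a / row_scale
  norm_c <- sqrt(sum(vapply(seq_len(nb), function(j)
    if (!is.null(C$mats[[j]])) sum(C$mats[[j]]^2) else 0, 0)) + sum(C$diag^2))

  xi <- max(10, sqrt(nt), max((1 + abs(b)) / (1 + norm_a)))
  eta <- max(10, sqrt(nt), max(c(norm_a, norm_c)) / sqrt(nt))
  X <- lapply(blocks, function(n) diag(xi, n)); xd <- rep(xi, ndiag)
  Z <- lapply(blocks, function(n) diag(eta, n)); zd <- rep(eta, ndiag)
  y <- numeric(m)

  inner <- function(P, Q) sum(P * Q)
  opA <- function(Xm, xdv) vapply(seq_len(m), function(i) {
    a <- A[[i]]; s <- 0
    if (nb) for (j in seq_len(nb)) if (!is.null(a$mats[[j]])) s <- s + inner(a$mats[[j]], Xm[[j]])
    if (length(a$diag)) s <- s + sum(a$diag * xdv[diag_idx(a)])
    s
  }, 0)
  opAt <- function(yv) {
    Mm <- lapply(blocks, function(n) matrix(0, n, n)); md <- numeric(ndiag)
    for (i in seq_len(m)) {
      a <- A[[i]]
      if (nb) for (j in seq_len(nb)) if (!is.null(a$mats[[j]]))
        Mm[[j]] <- Mm[[j]] + yv[i] * a$mats[[j]]
      if (length(a$diag)) md[diag_idx(a)] <- md[diag_idx(a)] + yv[i] * a$diag
    }
    list(mats = Mm, diag = md)
  }
  pobj_of <- function(Xm, xdv)
    sum(vapply(seq_len(nb), function(j)
      if (!is.null(C$mats[[j]])) inner(C$mats[[j]], Xm[[j]]) else 0, 0)) +
    sum(C$diag * xdv)

  # dense constraint matrix on the orthant part (m x ndiag), for the Schur term
  Ad <- matrix(0, m, ndiag)
  if (ndiag) for (i in seq_len(m)) {
    a <- A[[i]]
    if (length(a$diag)) Ad[i, diag_idx(a)] <- a$diag
  }

  status <- "max_iterations"
  best <- NULL
  it_done <- 0L
  stagnant <- 0L
  for (it in seq_len(max_iter)) {
    it_done <- it
    Zinv <- lapply(Z, function(M) tryCatch(solve(M), error = function(e) NULL))
    if (any(vapply(Zinv, is.null, TRUE))) { status <- "numerical_problems"; break }
    mu <- ((if (nb) sum(unlist(mapply(inner, X, Z, SIMPLIFY = FALSE))) else 0) +
             sum(xd * zd)) / max(nt, 1L)
    rp <- b - opA(X, xd)
    AtY <- opAt(y)
    Rd <- lapply(seq_len(nb), function(j)
      (if (!is.null(C$mats[[j]])) C$mats[[j]] else matrix(0, blocks[j], blocks[j])) -
        Z[[j]] - AtY$mats[[j]])
    rdd <- C$diag - zd - AtY$diag
    pobj <- pobj_of(X, xd); dobj <- sum(b * y)
    relgap <- abs(pobj - dobj) / (1 + abs(pobj) + abs(dobj))
    pres <- sqrt(sum(rp^2)) / (1 + sqrt(sum(b^2)))
    dres <- sqrt(sum(vapply(Rd, function(M) sum(M^2), 0)) + sum(rdd^2)) / (1 + norm_c)
    merit <- max(relgap, pres, dres)
    if (is.null(best) || merit < 0.95 * best$merit) {
      best <- list(X = X, xd = xd, y = y, Z = Z, zd = zd, merit = merit,
                   pobj = pobj, dobj = dobj, relgap = relgap,
                   pres = pres, dres = dres)
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant >= 12L) { status <- "stalled"; break }
    }
    if (verbose)
      cat(sprintf("it %3d mu %.2e gap %.2e pres %.2e dres %.2e pobj %.8g\n",
                  it, mu, relgap, pres, dres, pobj))
    if (merit < tol) { status <- "optimal"; break }
    if (mu < 1e-15 && merit < 1e-6) { status <- "optimal"; break }

    # Schur complement M[p,q] = sum_blk tr(Ap X Aq Zinv) + sum_d ap aq x/z
    Ms <- matrix(0, m, m)
    for (j in seq_len(nb)) {
      n <- blocks[j]
      act <- which(vapply(A, function(a) !is.null(a$mats[[j]]), TRUE))
      if (!length(act)) next
      V <- matrix(unlist(lapply(act, function(i) as.vector(A[[i]]$mats[[j]]))),
                  nrow = length(act), byrow = TRUE)
      W <- matrix(unlist(lapply(act, function(i)
        as.vector(t(X[[j]] %*% A[[i]]$mats[[j]] %*% Zinv[[j]])))),
        nrow = length(act), byrow = TRUE)
      Ms[act, act] <- Ms[act, act] + V %*% t(W)
    }
    if (ndiag) Ms <- Ms + Ad %*% (t(Ad) * (xd / zd))
    Ms <- .sdp_sym(Ms)
    shift <- 1e-13 * max(diag(Ms), 1)
    Mch <- tryCatch(chol(Ms + diag(shift, m)), error = function(e) NULL)
    if (is.null(Mch))
      Mch <- tryCatch(chol(Ms + diag(1e-8 * max(diag(Ms), 1), m)),
                      error = function(e) NULL)
    if (is.null(Mch)) { status <- "numerical_problems"; break }
    solveM <- function(r) {
      dy <- backsolve(Mch, forwardsolve(t(Mch), r))
      dy + backsolve(Mch, forwardsolve(t(Mch), r - Ms %*% dy))  # one refinement
    }

    direction <- function(nu, corr = NULL) {
      # M dy = b - nu A(Zinv) + A(X Rd Zinv) [+ A(corr Zinv)]
      XRdZ <- lapply(seq_len(nb), function(j) X[[j]] %*% Rd[[j]] %*% Zinv[[j]])
      corrZ <- if (!is.null(corr))
        lapply(seq_len(nb), function(j) corr$mats[[j]] %*% Zinv[[j]]) else NULL
      corrd <- if (!is.null(corr)) corr$diag / zd else NULL
      rhs <- vapply(seq_len(m), function(i) {
        a <- A[[i]]; s <- 0
        if (nb) for (j in seq_len(nb)) if (!is.null(a$mats[[j]])) {
          s <- s + inner(a$mats[[j]], XRdZ[[j]]) - nu * inner(a$mats[[j]], Zinv[[j]])
          if (!is.null(corrZ)) s <- s + inner(a$mats[[j]], corrZ[[j]])
        }
        if (length(a$diag)) {
          di <- diag_idx(a)
          s <- s + sum(a$diag * (xd[di] * rdd[di] - nu) / zd[di])
          if (!is.null(corrd)) s <- s + sum(a$diag * corrd[di])
        }
        s
      }, 0)
      dy <- solveM(b + rhs)
      dAtY <- opAt(dy)
      dZ <- lapply(seq_len(nb), function(j) Rd[[j]] - dAtY$mats[[j]])
      dzd <- rdd - dAtY$diag
      dX_raw <- lapply(seq_len(nb), function(j) {
        D <- nu * Zinv[[j]] - X[[j]] - X[[j]] %*% dZ[[j]] %*% Zinv[[j]]
        if (!is.null(corrZ)) D <- D - corrZ[[j]]
        D
      })
      dxd <- nu / zd - xd - xd * dzd / zd
      if (!is.null(corrd)) dxd <- dxd - corrd
      list(dy = dy, dX = lapply(dX_raw, .sdp_sym), dX_raw = dX_raw,
           dxd = dxd, dZ = dZ, dzd = dzd)
    }

    step_length <- function(Mlist, mvec, Dlist, dvec) {
      amax <- Inf
      for (j in seq_len(nb)) {
        L <- tryCatch(t(chol(Mlist[[j]])), error = function(e) NULL)
        if (is.null(L)) return(0)
        S <- forwardsolve(L, t(forwardsolve(L, Dlist[[j]])))
        lmin <- min(eigen(.sdp_sym(S), symmetric = TRUE, only.values = TRUE)$values)
        if (lmin < 0) amax <- min(amax, -1 / lmin)
      }
      if (length(mvec)) {
        neg <- dvec < 0
        if (any(neg)) amax <- min(amax, min(-mvec[neg] / dvec[neg]))
      }
      min(1, step_frac * amax)
    }

    aff <- direction(0)
    ap <- step_length(X, xd, aff$dX, aff$dxd)
    ad <- step_length(Z, zd, aff$dZ, aff$dzd)
    mu_aff <- ((if (nb) sum(unlist(mapply(function(Xj, Dj, Zj, Ej)
                 inner(Xj + ap * Dj, Zj + ad * Ej),
                 X, aff$dX, Z, aff$dZ, SIMPLIFY = FALSE))) else 0) +
               sum((xd + ap * aff$dxd) * (zd + ad * aff$dzd))) / max(nt, 1L)
    sigma <- min(max((max(mu_aff, 0) / mu)^3, 1e-10), 1)
    corr <- list(mats = lapply(seq_len(nb), function(j) aff$dX_raw[[j]] %*% aff$dZ[[j]]),
                 diag = aff$dxd * aff$dzd)
    stp <- direction(sigma * mu, corr)
    ap <- step_length(X, xd, stp$dX, stp$dxd)
    ad <- step_length(Z, zd, stp$dZ, stp$dzd)
    if (ap < 1e-10 && ad < 1e-10) { status <- "stalled"; break }
    X <- mapply(function(Xj, Dj) Xj + ap * Dj, X, stp$dX, SIMPLIFY = FALSE)
    xd <- xd + ap * stp$dxd
    Z <- mapply(function(Zj, Ej) Zj + ad * Ej, Z, stp$dZ, SIMPLIFY = FALSE)
    zd <- zd + ad * stp$dzd
    y <- y + ad * stp$dy
  }
  if (is.null(best))
    return(list(status = "numerical_problems", iterations = it_done))
  if (status %in% c("max_iterations", "stalled", "numerical_problems") &&
      best$merit < 1e-3)
    status <- paste0("inaccurate (", status, ")")
  list(X = best$X, xdiag = best$xd, y = best$y / row_scale, Z = best$Z,
       zdiag = best$zd,
       status = status, pobj = best$pobj, dobj = best$dobj, merit = best$merit,
       relgap = best$relgap, pres = best$pres, dres = best$dres,
       iterations = it_done)
}
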