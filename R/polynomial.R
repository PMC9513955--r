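#' Graded monomial basis
#'
#' Enumerates all exponent vectors `alpha` in `r` variables with total degree
#' at most `d`. The order is canonical throughout the package and in all
#' serialized polynomials: ascending total degree; within a degree,
#' lexicographically descending on `(alpha_1, ..., alpha_r)`, so for `r = 2`,
#' `d = 2` the order is `1, k1, k2, k1^2, k1*k2, k2^2`.
#'
#' @param r Number of variables, `r >= 1`.
#' @param d Total degree bound, `d >= 0`.
#' @return An integer matrix with `choose(r + d, r)` rows, one exponent vector
#'   per row.
#' @examples
#' basis_enumerate(2, 2)
#' n_coefficients(8, 2)  # 45
#' @export
basis_enumerate <- function(r, d) {
  r <- as.integer(r); d <- as.integer(d)
  if (is.na(r) || r < 1L) stop("r must be a positive integer")
  if (is.na(d) || d < 0L) stop("d must be a nonnegative integer")
  rows <- vector("list", d + 1L)
  for (deg in 0:d) rows[[deg + 1L]] <- .compositions_desc(deg, r)
  out <- do.call(rbind, rows)
  dimnames(out) <- NULL
  out
}

# all compositions of deg into r parts, lexicographically descending
.compositions_desc <- function(deg, r) {
  if (r == 1L) return(matrix(deg, 1L, 1L))
  out <- vector("list", deg + 1L)
  for (first in deg:0) {
    rest <- .compositions_desc(deg - first, r - 1L)
    out[[deg - first + 1L]] <- cbind(first, rest, deparse.level = 0L)
  }
  do.call(rbind, out)
}

#' @rdname basis_enumerate
#' @export
n_coefficients <- function(r, d) {
  r <- as.integer(r); d <- as.integer(d)
  if (is.na(r) || r < 1L) stop("r must be a positive integer")
  if (is.na(d) || d < 0L) stop("d must be a nonnegative integer")
  choose(r + d, r)
}

# index lookup: row index of each exponent vector within basis_enumerate(r, d)
.basis_key <- function(alpha) paste(alpha, collapse = ",")
.basis_index <- function(basis) {
  keys <- apply(basis, 1L, .basis_key)
  structure(seq_along(keys), names = keys)
}

#' Dense polynomials over the graded basis
#'
#' A polynomial of total degree at most `d` in `r` variables is stored as the
#' full coefficient vector over [basis_enumerate()] — exactly
#' `choose(r + d, r)` numbers, the storage format the superlevel-set
#' representation is built on.
#'
#' @param r Number of variables.
#' @param d Total degree bound.
#' @param coefficients Numeric vector of length `choose(r + d, r)` in the
#'   canonical basis order.
#' @return An object of class `dense_polynomial`.
#' @examples
#' p <- dense_polynomial(1, 2, c(1, 0, -1))  # 1 - x^2
#' poly_eval(p, 0.5)
#' @export
dense_polynomial <- function(r, d, coefficients) {
  r <- as.integer(r); d <- as.integer(d)
  n <- n_coefficients(r, d)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != n)
    stop(sprintf("expected %d coefficients for r=%d, d=%d, got %d",
                 n, r, d, length(coefficients)))
  structure(list(r = r, d = d, coefficients = coefficients,
                 basis = basis_enumerate(r, d)),
            class = "dense_polynomial")
}

#' @export
print.dense_polynomial <- function(x, ...) {
  cat(sprintf("<dense_polynomial r=%d d=%d (%d coefficients)>\n",
              x$r, x$d, length(x$coefficients)))
  nz <- which(abs(x$coefficients) > 0)
  show <- utils::head(nz, 8L)
  terms <- vapply(show, function(i) {
    a <- x$basis[i, ]
    mono <- paste0(ifelse(a > 0, paste0("k", seq_along(a),
                                        ifelse(a > 1, paste0("^", a), "")), ""),
                   collapse = "")
    sprintf("%+.4g%s", x$coefficients[i], if (nzchar(mono)) paste0("*", mono) else "")
  }, "")
  cat(" ", paste(terms, collapse = " "),
      if (length(nz) > 8L) " ..." else "", "\n")
  invisible(x)
}

#' Evaluate a dense polynomial
#'
#' @param p A `dense_polynomial`.
#' @param point Numeric vector of length `p$r`, or a matrix with one point per
#'   row.
#' @return Numeric scalar (or vector for a matrix of points).
#' @export
poly_eval <- function(p, point) {
  if (is.matrix(point)) {
    if (ncol(point) != p$r) stop("dimension mismatch")
    # monomial matrix: rows points, cols basis entries
    M <- matrix(1, nrow(point), nrow(p$basis))
    for (j in seq_len(p$r)) {
      e <- p$basis[, j]
      pos <- which(e > 0L)
      if (length(pos)) M[, pos] <- M[, pos, drop = FALSE] *
          outer(point[, j], e[pos], `^`)
    }
    return(as.numeric(M %*% p$coefficients))
  }
  if (length(point) != p$r) stop("dimension mismatch")
  mono <- apply(p$basis, 1L, function(a) prod(point^a))
  sum(p$coefficients * mono)
}

#' Exact monomial moments over a box
#'
#' Computes `integral over box of x^alpha dx` in closed form, the constants
#' that make the fitting objective `integral of p over B` a linear function of
#' the coefficients:
#' `prod_j (b_j^(a_j+1) - a_j^(a_j+1)) / (a_j+1)`.
#'
#' @param box A `hyperrectangle`.
#' @param alpha Integer exponent vector with one entry per coordinate.
#' @return The exact moment (numeric scalar).
#' @examples
#' monomial_integral(hyperrectangle(c(0, 0), c(1, 1)), c(1, 1))  # 1/4
#' @export
monomial_integral <- function(box, alpha) {
  alpha <- as.integer(alpha)
  if (length(alpha) != box_dim(box)) stop("dimension mismatch")
  if (any(alpha < 0L)) stop("exponents must be nonnegative")
  prod((box$upper^(alpha + 1) - box$lower^(alpha + 1)) / (alpha + 1))
}

#' @rdname monomial_integral
#' @param p A `dense_polynomial`; `poly_integral` integrates it over `box`.
#' @export
poly_integral <- function(p, box) {
  if (box_dim(box) != p$r) stop("dimension mismatch")
  w <- apply(p$basis, 1L, function(a) monomial_integral(box, a))
  sum(w * p$coefficients)
}

#' Compose a polynomial with an affine map
#'
#' Returns the dense polynomial `q` with `q(x) = p(scale * x + shift)`,
#' computed exactly at coefficient level by binomial expansion. Total degree is
#' preserved. This is how a superlevel-set polynomial fitted in rescaled
#' coordinates is transported back to the original parameter box.
#'
#' @param p A `dense_polynomial`.
#' @param map An [affine_map()] of the same dimension.
#' @return A `dense_polynomial` of the same `r` and `d`.
#' @export
affine_compose <- function(p, map) {
  if (length(map$scale) != p$r) stop("dimension mismatch")
  idx <- .basis_index(p$basis)
  out <- numeric(nrow(p$basis))
  for (i in which(p$coefficients != 0)) {
    a <- p$basis[i, ]
    # expand prod_j (s_j x_j + t_j)^(a_j) coordinate by coordinate
    terms_e <- matrix(0L, 1L, p$r); terms_c <- p$coefficients[i]
    for (j in seq_len(p$r)) {
      aj <- a[j]
      if (aj == 0L) next
      ks <- 0:aj
      wj <- choose(aj, ks) * map$scale[j]^ks * map$shift[j]^(aj - ks)
      keep <- which(wj != 0)
      ne <- terms_e[rep(seq_len(nrow(terms_e)), times = length(keep)), , drop = FALSE]
      ne[, j] <- ne[, j] + rep(ks[keep], each = nrow(terms_e))
      nc <- as.vector(outer(terms_c, wj[keep]))
      terms_e <- ne; terms_c <- nc
    }
    pos <- idx[apply(terms_e, 1L, .basis_key)]
    for (t in seq_along(pos)) out[pos[t]] <- out[pos[t]] + terms_c[t]
  }
  dense_polynomial(p$r, p$d, out)
}

#' Partial derivatives of a dense polynomial
#'
#' @param p A `dense_polynomial`.
#' @return A list of `r` dense polynomials (same `r`, degree `d`, padded), the
#'   gradient components.
#' @export
poly_grad <- function(p) {
  idx <- .basis_index(p$basis)
  lapply(seq_len(p$r), function(j) {
    out <- numeric(nrow(p$basis))
    for (i in which(p$coefficients != 0)) {
      a <- p$basis[i, ]
      if (a[j] == 0L) next
      b <- a; b[j] <- b[j] - 1L
      out[idx[[.basis_key(b)]]] <- out[idx[[.basis_key(b)]]] + p$coefficients[i] * a[j]
    }
    dense_polynomial(p$r, p$d, out)
  })
}

# scalar multiple / sum (internal helpers)
poly_scale <- function(p, s) dense_polynomial(p$r, p$d, s * p$coefficients)
poly_add <- function(p, q) {
  stopifnot(p$r == q$r, p$d == q$d)
  dense_polynomial(p$r, p$d, p$coefficients + q$coefficients)
}

#' Polynomial JSON serialization
#'
#' Layout: `{"r": int, "d": int, "basis": "graded-lex-desc",
#' "coefficients": [...]}` with full double precision; write-then-read is
#' bit-exact.
#'
#' @param p A `dense_polynomial`.
#' @param path File path.
#' @export
write_polynomial_json <- function(p, path) {
  jsonlite::write_json(
    list(r = jsonlite::unbox(p$r), d = jsonlite::unbox(p$d),
         basis = jsonlite::unbox("graded-lex-desc"),
         coefficients = p$coefficients),
    path, digits = I(17))  # 17 significant digits: doubles round-trip exactly
  invisible(path)
}

#' @rdname write_polynomial_json
#' @export
read_polynomial_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$basis, "graded-lex-desc"))
    stop("unsupported basis order: ", x$basis)
  dense_polynomial(x$r, x$d, x$coefficients)
}
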