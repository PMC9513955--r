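#' Count distinct positive real roots of a univariate polynomial
#'
#' The counting primitive behind every built-in parametric system: the number
#' of steady states of each worked example reduces to the number of distinct
#' positive real roots of a univariate polynomial. Roots are computed as the
#' eigenvalues of the (monic, coefficient-normalized) companion matrix.
#' Because the companion matrix is real, LAPACK returns real eigenvalues with
#' imaginary part exactly zero and complex ones in exact conjugate pairs, which
#' makes the real/complex classification far more reliable than generic
#' complex root finders near folds of the root set.
#'
#' Solutions are counted as a set (no multiplicity): real positive roots closer
#' than `merge_tol` (relative) are merged into one.
#'
#' @param coefficients Numeric coefficient vector in ascending degree order
#'   (`coefficients[i]` multiplies `x^(i-1)`). Trailing zeros are trimmed.
#' @param im_tol A root `z` counts as real when
#'   `abs(Im(z)) <= im_tol * (1 + abs(z))`.
#' @param pos_tol A real root counts as positive when `Re(z) > pos_tol`.
#' @param merge_tol Relative gap under which neighbouring real roots are
#'   treated as one solution.
#' @return Integer count of distinct positive real roots.
#' @examples
#' count_positive_roots_univariate(c(2, -3, 1))  # (x-1)(x-2): 2
#' count_positive_roots_univariate(c(1, 0, 1))   # x^2 + 1: 0
#' @export
count_positive_roots_univariate <- function(coefficients,
                                            im_tol = 1e-8,
                                            pos_tol = 1e-9,
                                            merge_tol = 1e-6) {
  x <- positive_roots_univariate(coefficients, im_tol, pos_tol)
  if (!length(x)) return(0L)
  sum(c(TRUE, diff(x) / pmax(1, abs(x[-1])) > merge_tol))
}

#' @rdname count_positive_roots_univariate
#' @return `positive_roots_univariate`: sorted numeric vector of the positive
#'   real roots (unmerged).
#' @export
positive_roots_univariate <- function(coefficients,
                                      im_tol = 1e-8,
                                      pos_tol = 1e-9) {
  co <- as.numeric(coefficients)
  if (!length(co) || all(co == 0)) stop("zero polynomial has no defined root count")
  deg <- max(which(co != 0)) - 1L
  if (deg == 0L) return(numeric(0))
  co <- co[seq_len(deg + 1L)]
  co <- co / max(abs(co))
  monic <- co / co[deg + 1L]
  A <- matrix(0, deg, deg)
  if (deg > 1L) A[cbind(2:deg, 1:(deg - 1L))] <- 1
  A[, deg] <- -monic[seq_len(deg)]
  z <- eigen(A, only.values = TRUE)$values
  keep <- abs(Im(z)) <= im_tol * (1 + abs(z)) & Re(z) > pos_tol
  sort(Re(z[keep]))
}

#' Sturm-sequence count of distinct real roots in an interval
#'
#' An independent sign-variation backend used to cross-check the companion
#' matrix counter on moderate degrees. Builds the Sturm chain by polynomial
#' long division (with coefficient normalization and a drop tolerance for
#' numerically vanishing remainders) and returns the number of distinct real
#' roots in `(a, b]`.
#'
#' @param coefficients Ascending coefficient vector.
#' @param a,b Interval end points, `a < b`; use a large `b` to count all
#'   positive roots.
#' @param drop_tol Relative magnitude under which a remainder is treated as
#'   zero (terminates the chain at a common factor).
#' @return Integer root count.
#' @export
sturm_count_interval <- function(coefficients, a, b, drop_tol = 1e-12) {
  stopifnot(a < b)
  trim <- function(p) {
    nz <- which(abs(p) > 0)
    if (!length(nz)) numeric(0) else p[seq_len(max(nz))]
  }
  co <- trim(as.numeric(coefficients))
  if (!length(co)) stop("zero polynomial")
  co <- co / max(abs(co))
  deriv <- function(p) if (length(p) <= 1L) numeric(0) else p[-1L] * seq_len(length(p) - 1L)
  prem <- function(num, den) {
    # remainder of polynomial division, coefficients ascending
    num <- trim(num); den <- trim(den)
    dn <- length(num) - 1L; dd <- length(den) - 1L
    while (dn >= dd && length(num)) {
      f <- num[dn + 1L] / den[dd + 1L]
      sub <- c(numeric(dn - dd), f * den)
      num <- num - sub
      num[dn + 1L] <- 0
      num <- trim(num)
      dn <- length(num) - 1L
    }
    num
  }
  chain <- list(co, trim(deriv(co)))
  while (length(chain[[length(chain)]]) > 1L) {
    rem <- prem(chain[[length(chain) - 1L]], chain[[length(chain)]])
    if (!length(rem) || max(abs(rem)) < drop_tol * max(abs(chain[[length(chain)]])))
      break
    chain[[length(chain) + 1L]] <- -rem / max(abs(rem))
  }
  sign_changes <- function(x) {
    vals <- vapply(chain, function(p) {
      s <- 0
      for (i in rev(seq_along(p))) s <- s * x + p[i]
      s
    }, 0)
    vals <- vals[vals != 0]
    if (length(vals) < 2L) return(0L)
    sum(diff(sign(vals)) != 0)
  }
  as.integer(sign_changes(a) - sign_changes(b))
}
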