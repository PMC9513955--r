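# Independent oracles used to cross-check package computations.

# Monte-Carlo integral of x^alpha over a box (checks the closed-form moments)
mc_monomial_integral <- function(box, alpha, n = 2e5, seed = 1) {
  pts <- sample_distribution(distribution_spec("uniform", box), n, seed)
  vals <- apply(pts, 1L, function(x) prod(x^alpha))
  list(value = mean(vals) * box_volume(box),
       se = stats::sd(vals) / sqrt(n) * box_volume(box))
}

# positive-root count via R's polyroot (independent of the companion backend)
polyroot_count_positive <- function(co, im_tol = 1e-7, merge_tol = 1e-6) {
  co <- co[seq_len(max(which(co != 0)))]
  z <- polyroot(co)
  keep <- abs(Im(z)) <= im_tol * (1 + abs(z)) & Re(z) > 1e-9
  x <- sort(Re(z[keep]))
  if (!length(x)) return(0L)
  sum(c(TRUE, diff(x) / pmax(1, abs(x[-1])) > merge_tol))
}

# root count by sign-change bracketing of a function on a fine grid
bracket_count <- function(f, lo, hi, n = 20000) {
  x <- seq(lo, hi, length.out = n)
  y <- vapply(x, f, 0)
  sum(diff(sign(y)) != 0 & y[-n] != 0)
}

# grid-search distance from k_star to the band {|p - 1| <= band} inside B;
# returns NA when the band misses the box or the minimiser touches the box
# boundary (there the band minimum is not a Lagrangian critical point)
grid_distance_oracle <- function(p, k_star, B, per_axis = 400, band = 1e-3) {
  g <- lapply(seq_len(box_dim(B)), function(j)
    seq(B$lower[j], B$upper[j], length.out = per_axis))
  pts <- as.matrix(expand.grid(g))
  vals <- poly_eval(p, pts)
  near <- abs(vals - 1) <= band
  if (!any(near)) return(NA_real_)
  sub <- pts[near, , drop = FALSE]
  d <- sqrt(rowSums((sub - matrix(k_star, nrow(sub), length(k_star),
                                  byrow = TRUE))^2))
  argmin <- sub[which.min(d), ]
  margin <- 2 * (B$upper - B$lower) / per_axis
  interior <- all(argmin > B$lower + margin) && all(argmin < B$upper - margin)
  if (!interior) return(NA_real_)
  min(d)
}

# exact expectation of a synthetic region oracle under an axis-aligned
# truncated normal (products of normal CDF differences)
exact_tn_expectation <- function(oracle, dist) {
  box <- dist$box
  sd <- sqrt(dist$variance)
  prob_box <- function(cell) {
    prod(vapply(seq_len(box_dim(box)), function(j) {
      lo <- max(cell$lower[j], box$lower[j]); hi <- min(cell$upper[j], box$upper[j])
      if (hi <= lo) return(0)
      (stats::pnorm(hi, dist$mean[j], sd[j]) - stats::pnorm(lo, dist$mean[j], sd[j])) /
        (stats::pnorm(box$upper[j], dist$mean[j], sd[j]) -
           stats::pnorm(box$lower[j], dist$mean[j], sd[j]))
    }, 0))
  }
  acc <- 0; covered <- 0
  for (cl in oracle$cells) {
    pr <- prob_box(cl$box)
    acc <- acc + cl$value * pr
    covered <- covered + pr
  }
  acc + oracle$background * (1 - covered)
}

# printed degree-2 superlevel-set polynomial of the S-system example,
# transcribed into the package's graded-lex-descending basis order
ssystem_printed_pss <- function() {
  dense_polynomial(3, 2, c(
    -8.112402,                       # 1
    1.226648, 1.271835, 0.710556,    # k1, k2, k3
    -0.043653, -0.082681, -0.045005, # k1^2, k1 k2, k1 k3
    -0.029919, -0.055895,            # k2^2, k2 k3
    -0.013650))                      # k3^2
}
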