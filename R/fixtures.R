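#' Two-parameter quintic system
#'
#' A univariate polynomial of degree 5 whose coefficients depend on two
#' parameters:
#' \deqn{f(x) = x^5 - (k_1 + 9/2)x^4 + (9/2 k_1 + 21/4)x^3 +
#'   (-23/4 k_1 + 3/8)x^2 + (15/8 k_1 - 23/8)x + (k_2/100 - 1/16).}
#' Depending on `(k1, k2)` the equation `f(x) = 0` attains between 0 and 5
#' positive solutions, which makes it a compact test bed for expected-count
#' estimation and the two-step bisection search: on
#' `B1 = [(0.5, 8), (1, 9)]` the count is identically 2, while
#' `B2 = [(2, 2), (2.5, 3)]` mixes regions with 1 and 3 positive roots whose
#' uniform average is still close to 2.
#'
#' @param domain Optional domain box (default `[(0, 0), (4, 10)]`, covering
#'   both rectangles above).
#' @return A [parametric_system()] with `r = 2`.
#' @examples
#' qs <- quintic_fixture()
#' count_positive_solutions(qs, c(0.75, 8.5))  # 2
#' @export
quintic_fixture <- function(domain = hyperrectangle(c(0, 0), c(4, 10))) {
  parametric_system(
    r = 2L,
    count = function(k) count_positive_roots_univariate(quintic_coefficients(k)),
    domain = domain,
    value_set = 0:5,
    name = "quintic")
}

#' @rdname quintic_fixture
#' @param k Parameter vector `(k1, k2)`.
#' @return `quintic_coefficients`: ascending coefficient vector of `f`.
#' @export
quintic_coefficients <- function(k) {
  c(k[2] / 100 - 1 / 16,
    15 / 8 * k[1] - 23 / 8,
    -23 / 4 * k[1] + 3 / 8,
    9 / 2 * k[1] + 21 / 4,
    -(k[1] + 9 / 2),
    1)
}

#' Reduced S-system gene expression network
#'
#' A four-species gene expression system with S-system (power-law / Hill)
#' kinetics whose right-hand sides are not rational functions. After fixing
#' all parameters except three degradation rates `(k1, k2, k3)`, its positive
#' steady states are in one-to-one correspondence with the positive roots of
#' the sparse degree-73 polynomial
#' \deqn{f(y) = c y^{73} - 144 y^{64} + 256 c y^9 - 12288, \quad
#'   c = (24 k_1^2 k_2 k_3^3)^{1/4},}
#' and by Descartes' rule of signs that polynomial has 1 or 3 positive roots
#' (with multiplicity) for every positive parameter choice. The default domain
#' is the cube `[(3, 1, 10), (7, 5, 14)]`.
#'
#' The returned system carries two extra routines used for validation:
#' `back_map(y, k)` maps a positive root `y` to the four concentrations
#' \deqn{(x_1, x_2, x_3, x_4) = (k_1 \sqrt{k_2 k_3 / 6}\, y^6,\;
#'   (k_2 k_3/6) y^{12},\; (k_3/3) y^{12},\; y^{16}),}
#' and `residual(x, k)` evaluates the four steady-state equations
#' at a state vector, so `residual(back_map(y, k), k)` should vanish at every
#' counted root.
#'
#' @return A [parametric_system()] with `r = 3` and fields `back_map`,
#'   `residual`, `coefficients`.
#' @examples
#' ss <- ssystem_fixture()
#' count_positive_solutions(ss, c(5, 3, 12))  # 3 (bistable point)
#' @export
ssystem_fixture <- function() {
  coefficients <- function(k) {
    if (any(k <= 0)) stop("parameters must be strictly positive (fourth root)")
    cc <- (24 * k[1]^2 * k[2] * k[3]^3)^(1 / 4)
    co <- numeric(74)
    co[74] <- cc; co[65] <- -144; co[10] <- 256 * cc; co[1] <- -12288
    co
  }
  sys <- parametric_system(
    r = 3L,
    count = function(k) count_positive_roots_univariate(coefficients(k)),
    domain = hyperrectangle(c(3, 1, 10), c(7, 5, 14)),
    value_set = c(1L, 2L, 3L),
    name = "ssystem")
  sys$coefficients <- coefficients
  sys$back_map <- function(y, k) {
    c(k[1] * sqrt(k[2] * k[3] / 6) * y^6,
      (k[2] * k[3] / 6) * y^12,
      (k[3] / 3) * y^12,
      y^16)
  }
  sys$residual <- function(x, k) {
    # first equation in cleared form: the production term 4 + 8 x4^4/(256 +
    # x4^4) balances the power-law degradation sqrt(x1 x3)/2
    c(4 + 8 * x[4]^4 / (256 + x[4]^4) - 0.5 * sqrt(x[1] * x[3]),
      x[1] - k[1] * sqrt(x[2]),
      2 * x[2] - k[2] * x[3],
      3 * x[3] - k[3] * x[4]^(3 / 4))
  }
  sys$positive_roots <- function(k) {
    positive_roots_univariate(coefficients(k))
  }
  sys
}

# LacI-TetR fixed rate constants (all parameters except k7, k8)
.lacitetr_k <- c(k1 = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 0.0082, k6 = 0.0149,
                 k9 = 0.01, k10 = 0.01, k11 = 10000, k12 = 10000, k13 = 2,
                 k14 = 25, k15 = 1, k16 = 9, k17 = 1, k18 = 1, k19 = 1, k20 = 4)

#' LacI-TetR gene regulatory network
#'
#' A twelve-variable steady-state system for a two-gene mutual-repression
#' circuit. With all rate constants fixed except `(k7, k8)` (the default box
#' is `[(0, 0), (0.1, 0.1)]`), ten of the twelve equations are linear in one
#' variable each and express every coordinate as a monomial multiple of
#' `(x7, x8)`; substituting them into the two conservation equations and
#' clearing denominators leaves a single degree-5 polynomial in `x8` whose
#' distinct positive roots are exactly the steady states. This deterministic
#' elimination replaces numerically solving the full system.
#'
#' The returned system carries `recover_state(v, k)` (full 12-coordinate state
#' from a root `v = x8`), `residual(x, k)` (the twelve equation residuals) and
#' `positive_roots(k)`.
#'
#' @param domain Domain box for `(k7, k8)`.
#' @return A [parametric_system()] with `r = 2`.
#' @examples
#' ls <- lacitetr_fixture()
#' count_positive_solutions(ls, c(0.05, 0.05))
#' @export
lacitetr_fixture <- function(domain = hyperrectangle(c(0, 0), c(0.1, 0.1))) {
  K <- .lacitetr_k
  poly_in_v <- function(k) {
    if (any(k <= 0)) stop("k7 and k8 must be strictly positive")
    b <- 1 / (K[["k6"]] * k[2])          # x4 = b * v * (k4=1)... times x2 scale
    a <- (K[["k9"]] / K[["k11"]]) * b    # x9 = a u v
    g <- 1 / (K[["k5"]] * k[1])          # x3 = g * u
    cc <- (K[["k10"]] / K[["k12"]]) * g  # x10 = cc u v
    # conservation 1: u * (1 + a v + 2 a b v^2) = k19 = 1  =>  u = 1/D1(v)
    # conservation 2: v * (D1^2 + cc D1 + (25/9) cc g) = k20 * D1^2
    D1 <- c(1, a, 2 * a * b)                       # ascending in v
    pmul <- function(p, q) {
      out <- numeric(length(p) + length(q) - 1L)
      for (i in seq_along(p))
        out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
      out
    }
    D1sq <- pmul(D1, D1)
    inner <- D1sq
    inner[1:3] <- inner[1:3] + cc * D1
    inner[1] <- inner[1] + (K[["k14"]] / K[["k16"]]) * cc * g
    lhs <- c(0, inner)                              # v * inner(v)
    lhs[seq_along(D1sq)] <- lhs[seq_along(D1sq)] - K[["k20"]] * D1sq
    lhs
  }
  recover_state <- function(v, k) {
    b <- 1 / (K[["k6"]] * k[2]); a <- (K[["k9"]] / K[["k11"]]) * b
    g <- 1 / (K[["k5"]] * k[1]); cc <- (K[["k10"]] / K[["k12"]]) * g
    u <- 1 / (1 + a * v + 2 * a * b * v^2)
    x1 <- u / K[["k5"]]; x2 <- v / K[["k6"]]
    x3 <- g * u; x4 <- b * v
    x9 <- a * u * v; x10 <- cc * u * v
    x11 <- (K[["k13"]] / K[["k15"]]) * x9 * x4
    x12 <- (K[["k14"]] / K[["k16"]]) * x10 * x3
    c(x1, x2, x3, x4, K[["k17"]], K[["k18"]], u, v, x9, x10, x11, x12)
  }
  residual <- function(x, k) {
    c(K[["k1"]] * x[7] * x[5] - K[["k5"]] * x[1],
      K[["k2"]] * x[8] * x[6] - K[["k6"]] * x[2],
      K[["k3"]] * x[1] - k[1] * x[3],
      K[["k4"]] * x[2] - k[2] * x[4],
      K[["k9"]] * x[7] * x[4] - K[["k11"]] * x[9],
      K[["k10"]] * x[8] * x[3] - K[["k12"]] * x[10],
      K[["k13"]] * x[9] * x[4] - K[["k15"]] * x[11],
      K[["k14"]] * x[10] * x[3] - K[["k16"]] * x[12],
      x[5] - K[["k17"]],
      x[6] - K[["k18"]],
      x[7] + x[9] + x[11] - K[["k19"]],
      x[8] + x[10] + x[12] - K[["k20"]])
  }
  sys <- parametric_system(
    r = 2L,
    count = function(k) count_positive_roots_univariate(poly_in_v(k)),
    domain = domain,
    value_set = 0:5,
    name = "lacitetr")
  sys$poly_in_v <- poly_in_v
  sys$recover_state <- recover_state
  sys$residual <- residual
  sys$positive_roots <- function(k) positive_roots_univariate(poly_in_v(k))
  sys
}

# autoreg fixed rate constants
.autoreg_k <- c(k1 = 2.81, k2 = 1, k4 = 0.98, k5 = 2.76, k6 = 1.55, k7 = 46.9)

#' Bistable autoregulatory motif
#'
#' A gene `X` whose protein product `P` dimerises (`2P <-> PP`) and binds the
#' gene (`X + PP <-> XPP`); both the free and the bound gene express `P`
#' (basal rate `k1`, enhanced rate `k7`), and `P` is degraded at rate `k2`.
#' The total amount of gene is conserved, `x1 + x4 = k8`. With the other rate
#' constants fixed (`k1 = 2.81`, `k2 = 1`, `k4 = 0.98`, `k5 = 2.76`,
#' `k6 = 1.55`, `k7 = 46.9`) and `(k3, k8)` free on
#' `[(0.0005, 0), (0.001, 2)]`, the steady states reduce to the positive roots
#' of the cubic
#' \deqn{k_2 c\, x^3 - k_7 k_8 c\, x^2 + k_2 x - k_1 k_8 = 0, \quad
#'   c = k_3 k_5 / (k_4 k_6),}
#' in the free protein concentration `x = x2`, so the network has 1 or 3
#' steady states away from fold points. The ODE right-hand sides were
#' reconstructed from the reaction scheme above; the reduction and parameter
#' values reproduce the published multistationary fractions within sampling
#' error (see the package vignette).
#'
#' @param domain Domain box for `(k3, k8)`.
#' @return A [parametric_system()] with `r = 2` and fields `cubic`,
#'   `recover_state`, `residual`.
#' @export
autoreg_fixture <- function(domain = hyperrectangle(c(0.0005, 0), c(0.001, 2))) {
  K <- .autoreg_k
  cubic <- function(k) {
    cc <- k[1] * K[["k5"]] / (K[["k4"]] * K[["k6"]])
    c(-K[["k1"]] * k[2], K[["k2"]], -K[["k7"]] * k[2] * cc, K[["k2"]] * cc)
  }
  recover_state <- function(x2, k) {
    cc <- k[1] * K[["k5"]] / (K[["k4"]] * K[["k6"]])
    x3 <- (k[1] / K[["k4"]]) * x2^2
    x1 <- k[2] / (1 + cc * x2^2)
    x4 <- k[2] - x1
    c(x1, x2, x3, x4)
  }
  residual <- function(x, k) {
    # steady-state equations of the motif plus the conservation law
    c(-K[["k5"]] * x[1] * x[3] + K[["k6"]] * x[4],
      K[["k1"]] * x[1] - K[["k2"]] * x[2] - 2 * k[1] * x[2]^2 +
        2 * K[["k4"]] * x[3] + K[["k7"]] * x[4],
      k[1] * x[2]^2 - K[["k4"]] * x[3] - K[["k5"]] * x[1] * x[3] +
        K[["k6"]] * x[4],
      x[1] + x[4] - k[2])
  }
  count <- function(k) {
    if (k[2] <= 0) return(0L)   # zero total gene: no positive steady state
    count_positive_roots_univariate(cubic(k))
  }
  sys <- parametric_system(r = 2L, count = count, domain = domain,
                           value_set = 0:3, name = "autoreg")
  sys$cubic <- cubic
  sys$recover_state <- recover_state
  sys$residual <- residual
  sys
}

#' Piecewise-constant synthetic region oracle
#'
#' A test double for the solution-count map: the count is `value_i` on the
#' i-th cell and `background` elsewhere in the box, so the expectation of the
#' count over any sub-box is available in closed form from overlap volumes.
#' Used to exercise representations and the bisection searches without any
#' root solving, and to check Monte-Carlo estimates against exact values.
#'
#' @param cells List of `list(box = <hyperrectangle>, value = <integer>)`,
#'   pairwise interior-disjoint and contained in `box`.
#' @param background Integer count outside all cells.
#' @param box Domain `hyperrectangle`.
#' @return A list of class `synthetic_region_oracle` with fields `system` (a
#'   [parametric_system()]) and `exact_expectation(sub_box)`.
#' @examples
#' orc <- synthetic_region_oracle(
#'   list(list(box = hyperrectangle(c(0, 0), c(0.5, 1)), value = 3)),
#'   background = 1, box = hyperrectangle(c(0, 0), c(1, 1)))
#' orc$exact_expectation(hyperrectangle(c(0, 0), c(1, 1)))  # 2
#' @export
synthetic_region_oracle <- function(cells, background, box) {
  stopifnot(inherits(box, "hyperrectangle"))
  background <- as.integer(background)
  for (cl in cells) {
    if (!inherits(cl$box, "hyperrectangle") || is.null(cl$value))
      stop("each cell must be list(box = hyperrectangle, value = integer)")
    if (!box_is_subset(cl$box, box)) stop("cell outside the domain box")
  }
  if (length(cells) > 1L) {
    for (i in seq_along(cells)[-1L]) for (j in seq_len(i - 1L)) {
      if (box_overlap_volume(cells[[i]]$box, cells[[j]]$box) > 0)
        stop("cells must have pairwise disjoint interiors")
    }
  }
  count <- function(k) {
    for (cl in cells) if (box_contains(cl$box, k)) return(as.integer(cl$value))
    background
  }
  exact_expectation <- function(sub_box) {
    stopifnot(inherits(sub_box, "hyperrectangle"))
    v <- box_volume(sub_box)
    acc <- 0; covered <- 0
    for (cl in cells) {
      ov <- box_overlap_volume(sub_box, cl$box)
      acc <- acc + cl$value * ov / v
      covered <- covered + ov / v
    }
    acc + background * (1 - covered)
  }
  vals <- sort(unique(c(background, vapply(cells, function(cl) as.integer(cl$value), 0L))))
  structure(list(
    system = parametric_system(r = box_dim(box), count = count, domain = box,
                               value_set = vals, name = "synthetic"),
    exact_expectation = exact_expectation,
    cells = cells, background = background, box = box),
    class = "synthetic_region_oracle")
}

#' Look up a built-in fixture by name
#'
#' @param name One of `"quintic"`, `"ssystem"`, `"lacitetr"`, `"autoreg"`.
#' @return A [parametric_system()].
#' @export
fixture_by_name <- function(name) {
  switch(name,
         quintic = quintic_fixture(),
         ssystem = ssystem_fixture(),
         lacitetr = lacitetr_fixture(),
         autoreg = autoreg_fixture(),
         stop("unknown fixture: ", name))
}
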