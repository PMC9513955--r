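Package: pssreg
Title: Polynomial Superlevel Set Representations of Multistationarity Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to describe the region of parameter space where a parametric
    system of equations (typically the steady-state system of a chemical
    reaction network) admits two or more positive solutions. The region is
    approximated from sampling or rectangular (grid / bisection) representations
    of the positive-solution count and then compressed into a polynomial
    superlevel set {k : p(k) >= 1}, where p minimises its integral over the
    parameter box subject to sum-of-squares positivity certificates. Includes
    positive-root counting for parametric polynomials, Monte-Carlo expected
    solution counts under uniform and truncated-normal distributions, two-value
    and two-step bisection searches driven by an expected-count oracle, an
    internal dense interior-point solver for the block-diagonal semidefinite
    programs behind the fits, and a Lagrange-multiplier distance from a
    parameter point to the fitted region boundary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
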