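Package: restraintopt
Title: Population-Adaptive Vehicle Restraint Design via Gaussian Process
    Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning occupant-adaptive vehicle restraint design
    policies from crash-simulation data. Provides maximum-projection
    space-filling designs of experiments over mixed occupant-covariate and
    restraint-design spaces, a seedable synthetic crash simulator emitting
    head, chest and femur injury measures, Gaussian-process surrogate models
    with squared-exponential ARD kernels and upper-confidence-bound
    prediction, anthropometrically scaled injury-risk curves combined into a
    joint injury probability, and gradient-based optimization of polynomial
    design policies that map occupant sex, stature and body-mass index to
    restraint settings, together with population, subgroup and per-variable
    sensitivity evaluation against non-adaptive baseline designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
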