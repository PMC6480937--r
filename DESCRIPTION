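Package: betasad
Title: A One-Parameter Continuum of Abundance Distributions Linking the
    Log Series and Zipf's Law
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the one-parameter family of species-abundance
    distributions whose curvature parameter beta interpolates between the
    ecological log series (beta = 1) and Zipf's law (beta -> 0).  The
    package provides the affine-invariant scale functions that define the
    family, numerically stable densities and normalization constants,
    constraint solvers that match a target mean abundance, exact and
    inverse-CDF samplers on both the abundance and the process
    (log-abundance) scale, maximum-likelihood fitting with endpoint model
    selection by AIC, rank-abundance (Zipf) slope regression, a
    proportional-growth process simulator, synthetic community
    generators, and a small command-line interface for fitting and
    sampling abundance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
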