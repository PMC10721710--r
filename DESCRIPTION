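Package: ecopula
Title: Copula-Based Screening of Directed and Non-Monotonic Associations
    in Ecological Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Community-wide screening of directed, possibly non-monotonic
    pairwise associations among ecosystem constituents (bacteria, fungi,
    plants, environment). Estimates the empirical checkerboard copula of
    each variable pair and derives the directed dependence measure q, the
    asymmetry a, and an index of monotonicity m that separates positive
    monotone, negative monotone, and non-monotonic relationships.
    Provides permutation significance tests, association-type profiles in
    (q, m) space with dynamic-range-box overlap and bootstrap-supported
    hierarchical clustering, directed ecosystem-coupling estimates
    against permutation null models, cumulative-sum-scaling count
    normalization, and a gradient-structured synthetic community
    generator with planted associations of known class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    biomformat,
    optparse
Config/testthat/edition: 3
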