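Package: rnaenm
Title: Elastic Network Models for RNA Flexibility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained elastic network models (ENMs) of RNA
    three-dimensional structures at eight bead granularities (any combination
    of phosphate, sugar and base interaction centers, or all heavy atoms),
    computes the network Hessian and its pseudoinverse covariance, mean square
    fluctuation profiles, Schur-complement effective interaction matrices for
    coarse-graining, and the root weighted square inner product (RWSIP)
    between essential dynamical spaces.  Includes ensemble-side tools
    (Kabsch superposition, ensemble covariance, cutoff scans against a
    conformer ensemble), a fully connected random-spring null model, analytic
    base-base distance-fluctuation profiles usable as a proxy for SHAPE
    chemical-probing reactivity, and deterministic synthetic fixtures
    (ideal duplexes, Gaussian conformer ensembles) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    MASS,
    knitr,
    rmarkdown
Config/testthat/edition: 3
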