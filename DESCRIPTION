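Package: dnacyclize
Title: Monte Carlo DNA Cyclization J-Factors for a Rigid-Basepair Elastic Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes DNA cyclization J-factors by half-molecule Monte Carlo within a
    coarse-grained rigid-basepair model with uniform diagonal stiffnesses, intrinsic
    twist, and planar or non-planar (helical) intrinsic bends. Chain closure is scored
    with a Euclidean tolerance on end-to-end distance and a rotation-invariant SO(3)
    distance normalized by the Haar measure. The downstream analysis layer fits
    cyclization profiles (log10 J versus length) to a piecewise-quadratic periodic
    form, regresses the fitted parameters against model knobs, constructs families of
    molecules with degenerate profiles, and calibrates many-parameter DNA models down
    to a stiffness scale and a twist-to-bend stiffness ratio.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
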