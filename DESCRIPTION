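Package: tabletlab
Title: Digital Formulation Design and Closed-Loop Compaction Optimisation
    for Direct-Compression Tablets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico platform for direct-compression tablet formulation
    development. Blend properties (densities, particle size and aspect ratio
    distributions, flow function coefficient) are predicted from raw-material
    records by mixture rules and a trainable ensemble regressor; tablet
    porosity and tensile strength are predicted with uncertainty by ensembles
    of feed-forward neural networks; a robust constrained genetic algorithm
    selects filler/binder excipients, their mass fractions and an initial
    compression pressure; and a physics-informed Bayesian optimisation agent
    refines the compression pressure against (virtual) experiments using
    Kawakita compressibility and Ryshkewitch-Duckworth compactability models,
    terminating when both fits stabilise. A virtual tableting plant with
    documented ground-truth compaction laws, dose and quality decision gates
    and Hotelling T-squared blend-homogeneity monitoring stands in for the
    make-and-test hardware, and supports end-to-end closed-loop studies and
    synthetic particle-size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
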