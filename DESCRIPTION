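Package: colexaffect
Title: Affective Norm Interpolation on Colexification Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted colexification networks from multilingual
    dictionary data (round-trip translations, shared translations, or
    CLICS-style concept edge lists), matches network nodes to affective
    norms lexica (valence, arousal, dominance), and interpolates ratings
    for unrated words by iterative neighbour-weighted means (harmonic
    propagation with rated words as boundary values). Includes the
    validation battery used to assess such interpolations: thresholded
    Pearson correlations with Fisher confidence intervals, 75/25 split
    cross-validation with Fisher-Z aggregation, degree-preserving
    random-neighbour and permuted-value null models, Hartigan's dip test
    for bimodality of neighbour-rating spread, a dominance-residual
    collinearity analysis, and language-threshold robustness sweeps.
    A synthetic-data generator with planted cluster structure makes the
    whole pipeline testable without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    stringi,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
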