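Package: forestcndd
Title: Conspecific Negative Density Dependence from Forest Stem Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quadrat-based estimation of conspecific negative density
    dependence (CNDD) from single-census forest stem maps.  Fits the
    Ricker recruitment model with negative-binomial error species by
    species, aggregates CNDD to plot level, computes species diversity
    indices, relates CNDD and diversity to environmental gradients with
    Spearman correlations and Poisson generalized linear models, and
    classifies species spatial patterns with the inhomogeneous pair
    correlation function against Monte-Carlo goodness-of-fit envelopes.
    Includes a synthetic multi-plot forest generator with known ground
    truth so that every stage of the pipeline can be verified by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
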