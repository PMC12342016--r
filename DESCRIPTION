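Package: paretoscope
Title: Pareto Task Inference for Transcriptomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Archetypal analysis of non-negative expression matrices under the
    Pareto optimality framework. Validates principal component analysis by
    eigenvalue permutation tests (Psi and phi statistics), fits the
    maximum-volume data-constrained simplex in principal component space,
    assesses its significance with the t-ratio randomization test, extracts
    positive and negative archetype-defining gene lists by an elbow rule on
    reconstructed gene-space coefficients, and characterizes archetypes by
    hypergeometric gene-set enrichment and by association with discrete and
    continuous sample attributes. Includes a seeded synthetic-data generator
    with planted simplex structure, defining genes and attribute gradients
    that serves as a ground-truth oracle for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
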