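Package: mgrf
Title: Module-Guided Random Forests for Integrative Genotype-Expression
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative regression of a quantitative trait on heterogeneous
    genomic variables (categorical genetic markers and continuous transcript
    abundances). Variables are organized into modules of a mixed-type
    correlation network (Pearson correlation, normalized mutual information)
    by modularity maximization; regression forests then draw candidate split
    variables through a two-stage, module-guided weighted sampling scheme
    that is iteratively re-weighted by learned module and variable
    importance. Provides corrected variable importance that redistributes
    importance among correlated within-module neighbours, module importance,
    a hypergeometric test of pairwise variable interactions based on
    co-occurrence of split variables across trees, simulators for F2
    intercross genotypes with linked markers and module-structured
    expression, and a paired cross-validation benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
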