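Package: faconnectome
Title: FA-Weighted Structural Connectome Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds fractional-anisotropy (FA) weighted white-matter
    structural networks from streamline-count and mean-FA connectivity
    matrices, sweeps them over a sparsity range, and computes the standard
    global and nodal graph-theory measures (clustering, path length,
    small-worldness against degree-preserving random nulls, global/local/
    nodal efficiency, degree and betweenness centrality) summarized as
    areas under the sparsity curve. Detects rich-club organization
    (coefficient curves, normalization by null ensembles, rich/feeder/local
    connection-class strengths) and provides the covariate-adjusted
    statistical layer used in case-control connectome studies: summary-
    statistics ANOVA, chi-square tests, ANCOVA-style group comparisons with
    post hoc contrasts and Benjamini-Hochberg FDR, and partial-correlation
    brain-behavior regression. Includes a seeded synthetic cohort generator
    emulating a three-group glioma study design (controls, frontal tumors,
    temporal tumors) for power analysis and pipeline validation, and an
    end-to-end pipeline driver with YAML configuration and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
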