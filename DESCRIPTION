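Package: sconet
Title: Structural Covariance Network Analysis of Regional Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-level structural covariance networks from regional
    cortical thickness or subcortical volume tables (FreeSurfer
    aparcstats2table/asegstats2table dialect), thresholds them across a
    density sweep under a connectedness constraint, computes graph-theory
    measures (Louvain modularity, transitivity, assortativity, clustering,
    node and edge betweenness), tests group differences with
    subject-reassignment permutation tests and false-discovery-rate
    correction, localizes affected connections with the network-based
    statistic, and predicts clinical severity scores from jackknife network
    features with cross-validated support vector regression. Includes a
    synthetic-cohort generator with plantable covariance effects so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
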