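Package: semip
Title: Multilevel Causal Network Inference for Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Causal inference tools for multi-omics genetic studies:
    additive-noise-model causation tests for discrete variables with
    permutation calibration, functional principal component summaries of
    genetic variants in gene regions, sparse structural equation models
    estimated by penalized two-stage least squares, score-based causal
    DAG learning by integer programming with cluster (acyclicity)
    constraints, joint multilevel genotype-methylation-expression-
    phenotype-disease networks, a simulation benchmark of power and
    false discovery rate for network recovery, and depth-first search
    of causal paths between omics nodes and disease nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    glmnet,
    yaml,
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
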