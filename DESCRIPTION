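Package: sccaclust
Title: Sparse Canonical Correlation Clustering for Imaging-Genetics Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint subtyping of two-view cohorts (e.g., regional PET uptake and
    SNP risk-allele dosages) by alternating sparse canonical correlation
    analysis and cluster-membership estimation. Provides L1-penalized (IPLS)
    and elastic-net penalized canonical-pair solvers with coordinate descent,
    simultaneous clustering with perturbation-based initialization,
    reproducibility machinery (intraclass correlation on binarized feature
    selections, initialization and bootstrap stability with co-assignment,
    longitudinal consistency), subtype profiling outputs, and a seeded
    synthetic-cohort generator with planted sparse canonical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mclust,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse
Config/testthat/edition: 3
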