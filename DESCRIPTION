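Package: groupknockoffs
Title: Second-Order Group Knockoffs for FDR-Controlled Group Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs second-order (Gaussian) group knockoffs for
    conditional-independence testing at the level of groups of correlated
    variables, as used in genome-wide association studies where linkage
    disequilibrium makes single-variant conditional inference underpowered.
    Provides solvers for the block-diagonal S matrix under maximum-entropy,
    minimum-variance-based-reconstructability and semidefinite-programming
    objectives for any number of knockoff copies, via coordinate descent with
    rank-one Cholesky maintenance alternating with eigenvector ("PCA")
    updates; the closed-form equivariant solution; group definition by
    average-linkage clustering of a correlation matrix; key-variable selection
    exploiting group-key conditional independence; knockoff sampling for
    individual-level designs and for GWAS summary-statistic Z-scores ("ghost"
    knockoffs); the multiple-knockoff selection filter; and a simulation
    harness measuring group power and false discovery rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
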