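Package: ibdmap
Title: Identity-by-Descent Mapping of Quantitative Traits with Sparse
    Variance-Component Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping quantitative-trait associations with
    identity-by-descent (IBD) sharing in large cohorts.  Builds sparse
    local and global IBD matrices from IBD-segment calls in genetic-map
    coordinates, fits a null linear mixed model with a block-diagonal
    IBD kinship matrix by restricted maximum likelihood, and tests each
    genomic window for a local IBD variance component.  P-values come
    from chi-square-mixture tail probabilities, with a finite-sample
    adjustment that accounts for the estimation of the residual
    variance, and a random-projection approximation that reduces each
    per-window eigenvalue problem to a small matrix so that a
    genome-wide scan scales linearly with sample size.  Includes
    conditional analysis against single-variant tag associations and
    simulators for IBD-segment cohorts, null and alternative
    phenotypes, and calibration/power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    parallel
Config/testthat/edition: 3
RoxygenNote: 7.3.3
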