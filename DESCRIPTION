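Package: twinewas
Title: Paired Epigenome-Wide Association Analysis for Disease-Discordant
    Monozygotic Twins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for DNA-methylation array studies of
    disease-discordant monozygotic twin pairs. Implements post-normalization
    quality control of beta-value matrices (detection-p masking, missingness
    filtering, k-nearest-neighbour imputation), reference-based deconvolution
    of nucleated blood-cell proportions by constrained projection, within-pair
    delta-beta statistics, per-probe conditional logistic regression for 1:1
    matched pairs fitted from the conditional likelihood, spatial-correlation
    (Stouffer-Liptak) differentially-methylated-region detection with Sidak
    regional correction, genomic-context-stratified coefficient-sign bias
    testing, and concordance statistics against orthogonal per-site assays.
    A synthetic twin-cohort generator with known ground truth makes every
    stage testable without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
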