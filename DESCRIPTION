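Package: overlapnet
Title: Overlapping Co-Expression Modules Associated with Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies treatment-responsive genes from paired
    control/treatment RNA-seq counts and phenotypes. Counts are normalized
    with median-of-ratios size factors and reduced to per-genotype log2
    fold-change profiles; a sign-agnostic co-expression network is built with
    WGCNA-style soft thresholding against a scale-free topology criterion;
    overlapping gene modules are detected with Hierarchical Link Clustering
    (link-community detection by single-linkage clustering of edge Jaccard
    similarities, cut at maximum partition density); module eigengenes are
    regressed on phenotype log-ratios with cross-validated LASSO to select
    trait-associated modules; selected genes are flagged as differentially
    expressed and validated with one-sided Fisher exact enrichment tests.
    Ships a synthetic-data generator with planted overlapping modules and
    causal traits for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    DESeq2,
    yaml,
    optparse
Config/testthat/edition: 3
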