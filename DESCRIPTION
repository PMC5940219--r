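Package: exdriver
Title: Expression-Informed Prioritization of Cancer Driver Mutations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes somatic driver mutations by regressing genome-wide
    tumor gene expression on binary mutation status with per-mutation
    adaptive L1 penalties derived from functional impact scores (e.g. GERP
    conservation and SIFT deleteriousness).  Each mutant allele is scored by
    the number of genes whose expression it associates with, and empirical
    p-values are assigned against a permutation null.  Includes the
    surrounding analysis toolkit: expression preprocessing (log2 and
    quantile normalization), differential expression by Mann-Whitney tests,
    hypergeometric gene-set enrichment, a mutation-frequency baseline,
    ROC/confusion evaluation, integrative prognostic scores with exact
    one-dimensional k-means consensus clustering and log-rank survival
    comparison, and a synthetic-data generator with planted sparse
    mutation-to-expression effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    survival,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
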