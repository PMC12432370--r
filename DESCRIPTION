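Package: igesbs
Title: Immunotherapy Response Signatures and Compound Boosting Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-cohort discovery of tumor-microenvironment gene expression
    signatures associated with immune-checkpoint-blockade response
    (per-cohort logistic regression pooled by DerSimonian-Laird
    random-effects meta-analysis), expansion of signatures to
    cancer-type-specific gene lists by tumor-purity-adjusted partial
    Spearman correlation with detectability filtering, an elastic-net
    response model with nested cross-validation, and in silico ranking of
    compounds by a weighted boosting score built from preranked GSEA of
    perturbation transcriptomes, cell-line weights and Cauchy-combination
    (ACAT) p-values. Includes a synthetic-data generator that emulates the
    statistical structure of the cohort, tissue and perturbation inputs so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    pROC,
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
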