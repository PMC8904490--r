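Package: regmir
Title: miRNA Regulator Inference from Recurrent Copy-Number Aberration Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers miRNA-gene regulatory interactions driven by recurrent
    somatic copy-number aberrations. From segmented copy-number profiles the
    package calls recurrently amplified/deleted regions (or ingests an external
    region table), assigns per-sample aberration status, computes region-wise
    negative-binomial differential expression from raw counts, annotates cis
    and trans genes, assembles multi-omics predictor sets (cis genes, cis
    miRNAs, gene-centric copy number, promoter methylation, transcription
    factors) and selects miRNA regulators of each trans gene by repeated
    cross-validated LASSO stability selection. Includes a synthetic multi-omics
    cohort generator with planted regulatory structure and the enrichment
    statistics (hypergeometric target enrichment, Fisher oncogenic-miRNA
    enrichment, method comparison, over-representation analysis) used to
    evaluate inferred networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    edgeR,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
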