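Package: epityper
Title: Context-Aware DNA Methylation Subtyping of Bulk Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for epigenetic subtyping of bulk tumor cohorts profiled
    on CpG methylation arrays. Adjusts beta values for tumor cell fraction per
    CpG and derives inferred in-silico normal estimates, annotates probes with
    gene-centric, CpG-density and open-chromatin contexts, discovers epitypes
    by non-negative matrix factorization of context-restricted high-variance
    CpGs, identifies differentially methylated CpGs with rank tests, links
    CpGs to nearby gene expression via jackknife Pearson correlation against
    an empirical randomized null, and extracts co-expression networks and
    metagene rank scores. Includes a synthetic cohort generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp, RcppArmadillo
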