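Package: gscsoma
Title: Somatic Transcriptome Reprogramming After Germline Stem Cell Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for bulk RNA-seq and phenotype studies of
    germline-ablated Caenorhabditis elegans. Implements a two-compartment
    (germline/soma) composition model that calibrates the fold-change cutoff
    for calling genes upregulated in the soma, a precision-weighted
    log-expression transform with empirical-Bayes moderated t-statistics, a
    min-|t| dependency screen with a randomized-t null and false discovery
    rate control, survival and categorical phenotype statistics
    (Kaplan-Meier, log-rank, summary-cell two-way interaction ANOVA,
    Holm-Sidak, chi-squared scoring), and stain-image quantification. A
    negative-binomial simulator with known ground truth generates all inputs
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
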