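Package: diaretseq
Title: RNA-Seq Differential Expression, Alternative Splicing, and Drug
    Response Analysis for Diabetic Retinopathy Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a bulk RNA-seq analysis workflow
    for streptozotocin-diabetic mouse retina and drug-treated diabetic
    retina: RPKM quantification against refFlat/GTF exon models, dual-route
    differential expression (permutation-based SAM d-statistic and one-way
    ANOVA with fold-change and p-value cutoffs), reciprocal-isoform
    alternative-splicing detection from junction read fractions (ASPIRE-style
    delta-I), and classification of drug responses into positive, negative,
    unresponsive, side-effect, and unaffected categories. Includes a
    negative-binomial count simulator with a planted-truth ledger so every
    stage is testable without raw sequencing data, and transcriptions of the
    study's published fold-change tables as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
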