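Package: cfTP53
Title: Detection of Emergent TP53 Resistance Mutations in Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for monitoring the emergence of TP53 resistance
    mutations in circulating cell-free DNA (cfDNA) from patients treated with
    HDM2 antagonists. Provides readers for per-strand variant tables (TSV and
    VCF 4.2), strand-bias quality scoring (ALT_RATIO), data-driven calibration
    of the variant-allele-frequency threshold from healthy-donor panels and
    matched tumour/plasma pairs, per-patient mutation-burden trajectories,
    transition/transversion spectrum tests, beta-binomial posterior predictive
    probabilities for detection counts, linear-log regression of tumour-size
    change on mutation burden, delta-delta-Ct relative copy-number calls, and a
    seeded synthetic cohort generator that emulates strand-biased sub-1% VAF
    artefact noise and logistic outgrowth of resistant subclones under drug
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
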