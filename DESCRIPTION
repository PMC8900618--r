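Package: pluriscan
Title: Genomic Characterization and Selection of Pluripotent Stem Cell Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a desk-scale pipeline for characterizing the genomes of
    human pluripotent stem cell lines from whole-genome sequencing summaries:
    read-depth scanning for large copy-number variants with mosaic cell-fraction
    estimation, B-allele-frequency detection of allelic imbalance and copy-neutral
    loss of heterozygosity, identity-by-descent relatedness and principal-component
    ancestry inference, polygenic-score normalization against a control cohort, a
    multi-stage deleterious-SNV prioritization cascade, intensity-rank-sum
    validation of CNV calls with false-discovery-rate estimation, recurrence
    analyses (minimal duplicated region, breakpoint motif search, burden
    regression), and per-line reporting with a tiered selection policy. A seeded
    synthetic-data generator emulates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    matrixStats,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
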