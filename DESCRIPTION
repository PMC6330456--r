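Package: exdiv
Title: Gene Expression Diversity and Selective-Sweep Analysis for
    Domestication Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares gene expression diversity between domestic species and
    their wild progenitors. Computes per-gene coefficients of variation on
    median-of-ratios normalized RNA-seq counts, the decrease-of-diversity
    statistic D_cv with one-sided t-tests, windowed selective-sweep scans
    (Nei's nucleotide diversity, Weir-Cockerham and Hudson Fst, pi-ratio)
    from two-population variant panels, candidate-selected-gene-set
    partitioning by sweep overlap, and joint enhancer-gene diversity
    synchrony classification. Includes a calibrated negative-binomial and
    allele-frequency simulator that plants known effects for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
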