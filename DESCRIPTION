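Package: dualscreen
Title: Internally Controlled Dual-Fluorescence CRISPR Depletion Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis and simulation of pooled CRISPR/Cas9 dropout screens
    that use a co-cultured (or co-transplanted) wild-type population as an
    internal control. Cas9-GFP and wild-type cells carrying the same guide
    are mixed, so knockout-driven depletion is read out either as a log2
    ratio of GFP-positive fractions between transduced and untransduced
    cells (the survival/proliferation score, from flow cytometry) or as a
    log2 fold change of per-library-normalized sgRNA read counts in sorted
    GFP-positive versus GFP-negative fractions (the abundance score, from
    amplicon sequencing). The package provides sgRNA library management, a
    stage-by-stage generative simulator of the whole screen (library
    representation, transduction, editing, growth, transplantation
    bottleneck, sorting, PCR and sequencing overdispersion,
    division-tracking dye assays), barcode counting from FASTQ,
    per-library CPM normalization, gene-level hit calling at a log2
    depletion threshold, screen QC, and percentile-based gene-set
    construction with hypergeometric overlap tests for meta-analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
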