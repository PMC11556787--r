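Package: degronscan
Title: Sort-Seq Discovery of ER-Luminal Degrons from Degenerate
    Pentapeptide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for FACS-seq (sort-seq) screens of degenerate
    pentapeptide reporter libraries read out with a tandem fluorescent timer
    (tFT). Provides genetic-code arithmetic and degenerate-codon null models,
    a ground-truth simulator for the full screen (library sampling, per-cell
    mCherry/GFP ratios, unstable-bin sorting, amplicon read generation),
    anchor-based extraction of the variable region from amplicon FASTQ,
    position-wise amino-acid frequency and fold-enrichment analysis against
    both the codon-usage null and the input library, candidate ranking, and
    exponential-decay half-life fitting for translation-shutoff chase series.
    All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
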