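Package: mycoTE
Title: Integrative Transposon, Methylome and Small RNA Analysis for Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the integrative regulatory-genomics analysis of
    transposable elements (TEs) in fungal genomes such as the arbuscular
    mycorrhizal fungus Rhizophagus irregularis: CpG-adjusted Kimura
    two-parameter divergence of TE copies and repeat landscapes, per-locus
    CpG methylation (mCG) scoring with symmetric-site merging and metagene
    profiles, rule-based gene classification into core/orphan/expanded
    classes, nearest-TE proximity statistics (Kruskal-Wallis with Dunn post
    hoc, Fisher exact enrichment), small RNA locus calling with
    treatment-enrichment classification, genomic-origin assignment and a
    shuffled-locus permutation null, plus expression filtering and a
    simplified differential test. A seeded synthetic-genome generator plants
    known truth (divergences, methylation components, gene classes, sRNA
    origins, fold changes) so every estimator can be validated by parameter
    recovery.
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
    stringr,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
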