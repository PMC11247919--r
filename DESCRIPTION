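Package: motifdisrupt
Title: Predict Disruption of Transcription Factor Binding Motifs by
    Sequence Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the effect of single-nucleotide variants, short
    insertions and deletions, and multi-allelic variants on transcription
    factor binding sites described by position weight matrices. Both the
    reference and the alternate allele sequence around a variant are
    scanned for the best motif match; the effect size is the difference
    between the two best normalized scores, and exact match p-values are
    computed by convolution of per-position score distributions. Motifs
    created or destroyed by indels are located in an indel-edge-relative
    coordinate system, results can be corroborated against a local
    ChIP-seq peak database, and exported as analyst tables or color-coded
    BED9 genome-browser tracks. A deterministic synthetic-fixture
    generator makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
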