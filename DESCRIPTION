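Package: tfshift
Title: Predicting the Effect of DNA Variants on Transcription Factor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the impact of short DNA variants (SNVs and small indels)
    on transcription factor binding sites. Binding models are position weight
    matrices (PWMs) derived from position count matrices, and transcription
    factor flexible models (TFFMs) - hidden Markov models with first-order
    dependencies between adjacent motif positions, in both first-order and
    detailed flavours. Each model is evaluated in a sliding window around the
    variant on the reference and the mutated sequence, on both strands; the
    two maximal window scores are combined into a signed joint score per
    model (-1 = likely binding-site loss, +1 = likely gain) and averaged per
    transcription factor. Includes readers for JASPAR-style count matrices,
    a TFFM XML dialect and a JSON model format, VCF and BED input, filter
    semantics for candidate regions, genes, coverage, zygosity and allele
    frequency, deterministic synthetic-fixture generators, and a command-line
    interface.
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
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
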