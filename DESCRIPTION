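Package: enhgain
Title: De Novo Enhancer Gain Detection from Trio Sequence-Activity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects de novo gained regulatory enhancers from
    human/macaque/ancestor sequence trios by combining comparative H3K27ac
    peak evidence with a convolutional sequence-to-activity scorer.
    Provides enhancer construction from peak intervals, ortholog pairing and
    trio-based gain/loss/conserved classification, in-silico combinatorial
    mutagenesis to find single-nucleotide essential mutations and minimal
    activating mutation sets, allele-specific read-count binomial tests for
    allelic imbalance, the direction-of-selection (DoS) statistic on
    McDonald-Kreitman style site tables with a fourfold-degenerate
    background, position-weight-matrix scanning with false-positive-rate
    calibrated thresholds, activator/repressor classification of
    transcription factors from binding-site gain/loss, and regulatory
    network inference with hierarchy summaries.  A fully seeded synthetic
    data generator produces ground-truthed sequence trios, allele count
    tables, site tables and expression matrices so that every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
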