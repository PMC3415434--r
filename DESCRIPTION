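Package: tailslip
Title: Hallmark Characterization and A-Tail Slippage Analysis of De Novo
    SINE Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for de novo retroelement (Alu/SINE)
    insertions recovered from culture-based rescue assays. Recovers the
    hallmarks of target-primed reverse transcription (target-site
    duplications, L1 endonuclease consensus scoring, 5' truncation,
    atypical-event classification, body mismatch scanning), segments
    disruption-tagged A-tails against their parental template to infer
    TPRT priming location and per-segment expansion, simulates slippage
    during reverse transcription of homopolymeric tails, places random
    insertions in karyotype copy-number-weighted integer space, and tests
    genomic-window feature enrichment with permutation-calibrated
    Mann-Whitney-Wilcoxon statistics. A synthetic-data module generates an
    annotated multi-chromosome fixture genome and simulated insertion
    cohorts with full ground truth so every stage runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
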