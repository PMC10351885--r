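Package: editscreen
Title: Dual-Enzyme RNA Editing Site Identification for TRIBE and STAMP
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@editscreen.dev", role = c("aut", "cre"))
Description: Identifies RNA editing sites produced by RNA-binding-protein
    deaminase fusions (TRIBE: RBP-ADARcd, A-to-G; STAMP: RBP-APOBEC1, C-to-T)
    from per-position nucleotide count matrices or coordinate-sorted
    alignments. Screens a no-enzyme control for editable positions, thresholds
    experimental samples on coverage and edited-read fraction, merges
    biological replicates with an enzyme-appropriate rule (exact match for
    ADAR, 100-bp proximity for APOBEC), subtracts enzyme-only background, and
    characterises the resulting site sets: sites per transcript, editing
    fraction statistics with a Wilcoxon rank-sum test, trinucleotide context
    profiles, 5'UTR/CDS/3'UTR fold enrichment with proportion tests,
    3'-directed site shifting, per-million depth normalisation, interval
    expansion/overlap, and fixed-motif region scans. Ships a deterministic
    synthetic-data generator (genome, transcript models, control/enzyme-only/
    fusion count matrices with planted editing ground truth) so every pipeline
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
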