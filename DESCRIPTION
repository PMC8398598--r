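Package: nbpanel
Title: Targeted Hybrid-Capture Panel Analysis for Neuroblastoma Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for high-depth hybrid-capture panel
    sequencing of neuroblastoma. Calls copy-number alterations from binned
    depth ratios against diploid technical controls, detects rearrangements
    from discordant read pairs with clipped-read breakpoint refinement,
    merges structural-variant call sets from multiple callers by a
    windowed consensus rule, calls single-nucleotide variants with variant
    allele frequencies from high-depth pileups, and aggregates marker calls
    into telomere-maintenance status and ultra-high-risk classification.
    Includes a paired-end alignment simulator that emits reference FASTA,
    coordinate-sorted SAM and a machine-readable truth set, so every caller
    is testable end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    jsonlite,
    stats,
    graphics,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
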