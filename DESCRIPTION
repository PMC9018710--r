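Package: piRcleave
Title: Sequence Preferences at piRNA 5' Ends and Phased Biogenesis Simulation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies nucleotide and trinucleotide preferences at the 5'
    ends of PIWI-interacting RNAs (piRNAs) produced through Zucchini/PLD6
    phased biogenesis. Implements a windowed 5' end definition score that
    measures how strongly each precursor position competes with its
    neighbours for cleavage, score binning and bin-wise sequence
    composition, motif enrichment around preferred cleavage sites,
    stop-codon enrichment statistics with resampling and exact tests, open
    reading frame classification of stop codons, per-base conservation and
    variant joins, and cross-species robustness classification with
    trinucleotide composition normalization. A seeded generator of phased
    tail-to-head pre-piRNA reads with known cleavage weights provides
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    BiocGenerics,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
biocViews: Sequencing, SmallRNA, Coverage, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
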