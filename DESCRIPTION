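Package: knockin
Title: Design and Sequencing-Based Verification of Markerless CRISPR/Cas9
    Knock-Ins in Komagataella phaffii
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico toolkit for hierarchical Golden Gate assembly of
    CRISPR/Cas9 donor-helper constructs with fixed fusion sites and 500-bp
    homology arms, and for verifying the resulting Komagataella phaffii
    knock-in clones from whole-genome sequencing depth. Includes type IIS
    digestion and ligation-graph assembly simulation, restriction-site
    scrubbing and codon optimization, a synthetic clone and read generator
    with known ground truth, read-depth transgene copy-number estimation
    relative to a single-copy calibrator, junction-orientation
    classification at regenerated cohesive-end sites, terminal
    chromosome-loss detection, and microplate fluorescence and growth
    analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
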