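Package: nickrepair
Title: Repair-Outcome Analysis for Nick- and Break-Induced Recombination Reporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to quantify repair outcomes of Cas9- and Cas9
    nickase-induced DNA lesions in single-copy recombination reporters:
    junction indel and microhomology calling from amplicon deep-sequencing
    reads, NHEJ-reporter reading-frame restoration, translocation junction
    detection and relative quantification against an internal control,
    structural classification of tandem-duplication products into
    invasion/termination classes, replication-fork collision strand logic
    for nickase-induced one-ended breaks, and FACS-based STGC/LTGC
    frequency normalization with strand-asymmetry aggregation.  A
    synthetic-data generator emulates the reporter constructs, amplicon
    libraries, translocation libraries, clone sequences and FACS count
    tables with per-record ground truth, so that every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
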