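Package: RCAssembly
Title: Fosmid Insert Assembly from Rolling-Circle-Amplified Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: De novo assembly of fosmid insert sequences from phi29
    rolling-circle-amplified, nanopore-style long reads. Trims vector
    backbone matches out of reads to resolve amplification concatemers,
    assembles the vector-free fragments with a coverage-gated greedy
    overlap-layout-consensus assembler, selects the primary contig and
    finishes it into a linear insert oriented at the multiple-cloning
    site. Includes a native k-mer anchored local aligner, in-silico
    restriction digestion, QC metrics, host-contamination flagging, and a
    rolling-circle read simulator that models concatemer and chimera
    artifacts with per-read truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
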