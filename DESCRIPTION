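Package: permacirc
Title: Discovery of Permuted Circular Non-Coding RNA Genes from Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects permuted non-coding RNA genes whose mature transcripts
    are circularized end-to-end, as found for the signal recognition particle
    (SRP) RNA of Thermoproteus tenax. Provides degenerate-motif and
    folding-potential scanning to nominate candidate loci, a seed-and-extend
    local aligner with soft-clip bookkeeping, circularization-junction calling
    from soft-clipped reads, transcription start site and TATA-box inference
    for the precursor, and detection of the bulge-helix-bulge (BHB) processing
    motif that explains the mature termini. A synthetic-locus and read
    generator with full ground-truth annotation makes every stage testable
    without access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
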