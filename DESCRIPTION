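Package: psiseq
Title: Detection of Pseudouridine in Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting pseudouridine (Psi) in
    small RNAs from three complementary assay designs: immunoprecipitation
    with an anti-pseudouridine antibody (Psi-IP enrichment of bound versus
    unbound fractions), CMC treatment which blocks reverse transcription and
    depletes Psi-containing reads, and CMC with Mn2+ reverse transcription
    which converts the block into mismatches and deletions at Psi residues.
    Includes a synthetic small RNA library generator with known Psi ground
    truth (multi-class pools of miRNA, tRNA fragments, rRNA fragments,
    transposon siRNA size classes and piRNA-like reads, with enzyme-specific
    sites for PUS7/UNUAR, PUS10/position-55 and DKC1), FASTQ preprocessing,
    a loci-scale read aligner tolerant of modification-induced mismatches and
    deletions, a paired negative-binomial enrichment engine with
    median-of-ratios normalization and Wald tests, position-level
    mismatch/deletion site calling, and biological feature classification
    (tRNA fragment anatomy, transposon family size classes, piRNA clusters,
    Argonaute preference, terminal nucleotide bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    MASS,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
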