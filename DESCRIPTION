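Package: lrasm
Title: Overlap-Layout-Consensus Assembly of Noisy Long Reads
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular overlap-layout-consensus (OLC) assembler for noisy
    long single-molecule reads (PacBio CLR / Oxford Nanopore style, 5-20%
    indel-dominated error). Overlapping uses homopolymer-compressed (HPC)
    k-mer indexing with occurrence filtering and hash subsampling, z-mer
    anchor chaining in sliding windows with a repeat-depth weighting
    scheme, and piecewise banded global alignment with a dynamic band.
    Trimming clips low-support read ends and removes chimeric reads by
    spur statistics and overlap-graph structure. Layout builds a
    Best-Overlap-Graph with near-best edge selection and emits unitigs;
    consensus threads member reads through a backbone-anchored alignment
    DAG and calls the heaviest path. A seeded simulator of genomes and
    noisy reads with ground-truth overlaps supports end-to-end testing
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
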