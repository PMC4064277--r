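Package: contalign
Title: Optimal Pairwise Alignment with Nonlinear Contiguity Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generalized optimal local and global pairwise alignment of
    nucleotide sequences in which runs of contiguous matching bases are
    scored by an arbitrary nondecreasing function (cubic by default),
    implemented as dynamic programming over a three-dimensional edit graph
    with on-demand contiguity depth. The classic Smith-Waterman (SW) and
    gap-affine Smith-Waterman (SWGA) schemes are recovered exactly under a
    linear scoring function. Includes banded alignment, a check-pointed
    linear-space traceback, multi-genome alignment-consistency metrics
    (per-position agreement profiles, conserved contiguous elements, k-mer
    tallies), a synthetic ortholog-family simulator with planted conserved
    motifs, and a brute-force path-enumeration oracle for validation.
License: MIT
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
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Alignment, SequenceMatching, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'scoring.R'
    'align.R'
    'io.R'
    'consistency.R'
    'simulate.R'
    'cli.R'
    'contalign-package.R'
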