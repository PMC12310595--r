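Package: TriContact
Title: Multi-Contact 3C Viewpoint Profiles, Three-Way Contact Matrices and
    VP-SOI Cooperativity Testing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of viewpoint-primed multi-contact chromosome
    conformation capture (3C-HTGTS / MC-4C style) libraries, in which each
    sequencing read is a concatemer of ligated restriction fragments anchored
    at a bait (viewpoint) fragment.  Provides an in-silico restriction digest
    with exact-match fragment assignment, decomposition of reads into ordered
    fragment chains with self-ligation, off-target and continuous-fragment
    filtering, viewpoint-anchored pairwise profiles with counts-per-million-
    in-cis normalization, binned three-way contact matrices with total-count
    normalization, subtraction and loop calling, and a resampling z-score
    test that classifies third sites as cooperative, random or competitive
    given a viewpoint and a second site of interest.  A synthetic concatemer
    library generator with planted distance decay, cooperative/competitive
    triads and boundary insulation provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Epigenetics, HiC, Sequencing, Software
RoxygenNote: 7.3.3
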