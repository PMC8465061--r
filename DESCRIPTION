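Package: selexscan
Title: REPSA Selection Simulation, Dyad Motif Discovery and Genome Scanning
    for Transcription Factor Consensus Definition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the reverse-genetic definition of a transcription
    factor DNA-binding consensus from iterative in vitro selection
    (REPSA/SELEX) data. Simulates selection rounds over randomized-core
    template libraries under a single-site occupancy model, refines and
    deduplicates selection-round sequencing reads, discovers ungapped motifs
    by ZOOPS expectation-maximization with an optional palindromic
    constraint, builds palindromically extended letter-probability matrices
    in MEME minimal motif format, scans genomes for motif occurrences with
    exact dynamic-programming p-values, Benjamini-Hochberg q-values and
    promoter-window annotation, fits 1:1 association-then-dissociation
    biosensor kinetics globally across analyte concentrations, and
    quantifies restriction-protection (REPA) titrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
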