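Package: smfkinetics
Title: Promoter-State Decomposition and Pol II Kinetics from
    Single-Molecule Footprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to sort single-molecule footprinting (SMF) reads at
    promoters into occupancy states (nucleosome, unbound, PIC, PIC + Pol II,
    Pol II, unassigned) from bin-wise methylation patterns, to link the
    resulting state frequencies to effective transcription kinetics through
    a three-state stochastic promoter model with a closed-form steady state,
    and to estimate promoter-proximal Pol II turnover rates from
    spike-in-normalised nascent-transcription time courses by
    Poisson-likelihood exponential-decay fitting. Includes TSS refinement
    against CAGE peaks, TATA-box annotation, strand-aware window counting,
    pausing indices, and a synthetic-data generator with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    Matrix,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
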