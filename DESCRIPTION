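Package: cutfoot
Title: Cut-Matrix Estimation and Motif Footprinting for CUT&RUN Data
Version: 0.1.0
Authors@R:
    person("cutfoot", "developers", email = "cutfoot@example.org",
           role = c("aut", "cre"))
Description: Processing and footprint analysis for paired-end CUT&RUN
    experiments. Builds strand-specific single-nucleotide cut matrices
    around oriented motif occurrences, fits a two-component bound/unbound
    mixture model (negative-binomial read totals, multinomial spatial
    profile) to obtain per-site binding log-odds, scores footprint
    symmetry to separate primary from secondary (co-factor) motifs, calls
    direct binding sites inside peaks, trims short adapter read-through
    overhangs missed by template trimmers, and computes quality-control
    metrics. Includes a synthetic fragment and FASTQ simulator so that
    every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
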