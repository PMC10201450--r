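Package: g4bulge
Title: Genome-Wide Discovery and Validation of Bulged G-Quadruplex Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scanners for canonical G-quadruplex motifs and for bulged
    G-quadruplex sequence models (G3B1, G3B2, G2B2) on both genome strands,
    with the filtering and strand-specific merging rules used to derive
    non-canonical G4 regions; gene-segment annotation and anchored
    per-nucleotide frequency profiles; background-matched enrichment
    statistics against experimental peak sets; Kolmogorov-Waring fitting of
    per-gene motif counts; and diagnostic-accuracy evaluation of model
    predictions against experimental G4-formation calls. Includes a
    synthetic-data generator (genomes, gene models, planted motifs) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
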