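Package: plastopart
Title: Quadripartite Structure, IR-Junction Typing and Gene Degradation in Plastid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis of annotated circular plastid
    genomes (plastomes): detection of the large inverted repeat and
    partitioning into LSC/IRb/SSC/IRa, profiling and typing of the IR-SSC
    junctions (Type A/B/C by the ycf1 portion held in IRa), reconstruction of
    IR-expansion events and their putative mechanisms (short gene-conversion
    versus long double-strand-break copy repair), classification of
    protein-coding genes as intact, putative pseudogene, lost or uncertain,
    mismatch-tolerant dispersed-repeat scanning and perfect tandem-repeat
    detection, comparative reporting, and a synthetic-plastome generator with
    machine-readable truth tables so every pipeline stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
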