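Package: fapkit
Title: Operon Mining, Repeat Motifs and Fibril Biophysics for Fap Functional Amyloids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the computational characterization of Fap-type
    bacterial functional amyloids. Mines fap operons from HMMER3 homology
    hit tables and gene coordinate tables, censuses imperfect repeats in
    FapB/FapC genes, builds position frequency matrices, sequence-logo
    information content and consensus motifs from aligned repeats, performs
    helical-symmetry arithmetic (rise/twist/crossover) and fibril assembly
    from atomic monomers, models small-angle X-ray scattering of fibrils
    with an elliptical-cylinder plus Gaussian-chain form factor and by the
    Debye equation with an explicit hydration layer, and estimates fibril
    twist periodicity from atomic force microscopy height profiles by
    Fourier analysis. Includes seeded synthetic-data generators for every
    input so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    bio3d,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph
Config/testthat/edition: 3
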