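Package: hijackscan
Title: Enhancer-Hijacking Analysis of Rearranged Genomes with 4C-seq
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to analyse enhancer hijacking by chromosomal
    translocations at desk scale. Provides in-silico restriction digestion
    into primary/secondary fragment maps, processing of circular chromosome
    conformation capture (4C-seq) reads into per-fragment contact profiles
    (demultiplexing, primer clipping, fragment-end assignment, viewpoint
    exclusion), reads-per-million normalisation and running-mean smoothing
    with WIG/bedGraph export, a minimal discordant-pair plus split-read
    translocation breakpoint caller, derivative-chromosome construction with
    exact bidirectional coordinate maps, CTCF motif-orientation convergence
    analysis, an enhancer-docking-site preservation test, and enhancer-module
    read quantification. A synthetic-data module simulates toy rearranged
    genomes, 4C libraries with power-law contact decay and loop enrichment,
    and junction-spanning capture read pairs, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    zoo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, Sequencing, StructuralVariation, Coverage
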