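Package: LysisTyper
Title: Lysis-Module Mining and Typing for Annotated Phage Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies holin and endolysin genes in annotated bacteriophage
    genomes, delineates lysis modules and classifies their gene organization
    against a configurable catalogue, types endolysin domain architectures
    (enzymatically active and cell-wall-binding domains, frequency-ranked),
    detects overprinted gene overlaps, and characterizes holins by
    hydropathy-based transmembrane-segment prediction and transporter-family
    assignment. Ships a synthetic phage-genome generator with planted ground
    truth so the whole analysis runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Annotation, FunctionalPrediction, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'lexicons.R'
    'utils.R'
    'endolysin-architecture.R'
    'gene-overlap.R'
    'genome-io.R'
    'holin-characterization.R'
    'module-delineation.R'
    'panel-selection.R'
    'synthetic-data.R'
    'role-classification.R'
    'pipeline.R'
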