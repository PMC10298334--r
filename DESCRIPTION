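Package: meltmark
Title: In Silico PCR, RFLP and High-Resolution Melting Workflows for
    Mitochondrial Species Markers
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating DNA-based species
    identification assays on mitochondrial markers, with the Sparidae
    (sea bream) fish panel as the worked system. Implements degenerate-primer
    in silico PCR on linear and circular templates, multiplex product
    pattern prediction, restriction-digest (PCR-RFLP) fragment patterns
    with gel-tolerant band matching, nearest-neighbor duplex thermodynamics
    with a calibrated primer melting-temperature convention, amplicon melt
    curve simulation, high-resolution melting (HRM) curve normalization and
    two-stage clustering with per-sample confidence, alignment scanning for
    short diagnostic marker windows with conserved primer flanks, and a
    deterministic synthetic-panel generator so the full workflow runs and
    tests without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, SequenceMatching, Clustering, Classification
Collate: 
    'iupac.R'
    'AllClasses.R'
    'accessors.R'
    'thermo.R'
    'assay_design.R'
    'hrm.R'
    'insilico_pcr.R'
    'meltmark-package.R'
    'rflp.R'
    'synth.R'
    'pipeline.R'
    'seqio.R'
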