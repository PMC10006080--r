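Package: mef2dyn
Title: Dynamics, Phase Behaviour and Activity Analysis of MEF2D Beta-Domain Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage analysis pipeline for studying how the dynamics of
    the alternatively spliced, seven-residue acidic beta-domain of the MEF2D
    transcription factor shapes its higher-order assembly and transcriptional
    activity. Provides sequence-window aggregation of per-residue disorder,
    fuzzy-binding and droplet-promoting probabilities with variant scoring and
    droplet-landscape placement; contact-map-similarity clustering of
    disordered-peptide molecular dynamics ensembles with per-cluster contact
    maps and domain contact fractions; NMR dynamics fitting (secondary shifts,
    random coil index order parameters, T1/T2 relaxation, reduced spectral
    densities, DOSY diffusion); FRAP double-normalization with recovery
    kinetics and mobility classification; differentiation and reporter-assay
    metrics; and a seeded synthetic-data generator with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
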