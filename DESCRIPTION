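Package: cachesense
Title: Pocket-Signature Screening of dCache_1 Sensor Domains and One-Site
    ITC Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying candidate autoinducer-2 (AI-2) receptors
    among dCache_1 extracytoplasmic sensor domains. Anchors family multiple
    sequence alignments to PctA reference numbering, screens members for the
    five-residue binding-pocket signature (R126, W128, Y144, D146, D173),
    profiles per-position conservation (position frequency matrices and
    information content in bits), classifies proteins into signal-transduction
    families from Pfam-style domain architectures with taxonomy rollups, and
    simulates and fits one-site isothermal titration calorimetry (ITC)
    isotherms with displacement dilution and heat-of-dilution correction.
    Synthetic-data generators with ground-truth labels make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
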