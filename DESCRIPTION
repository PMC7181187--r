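Package: axoquant
Title: Quantification of Chandelier-Cell Axo-Axonic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for measuring axo-axonic (chandelier cell)
    synaptic plasticity: axon initial segment (AIS) morphometry from
    fluorescence intensity profiles, bouton/cartridge quantification and
    connection probability within a soma-centered cylinder, perisomatic
    synapse counting from two-channel immunofluorescence, cfos activity
    classification, patch-clamp feature extraction (input-output curves,
    jerk-based spike threshold, evoked PSC amplitude and failure rate,
    template-matched spontaneous PSC detection), and voltage-indicator
    trace processing (camera-noise subtraction, double-exponential bleach
    correction, dF/F, Z-score event detection and response-polarity
    classification). Includes seeded synthetic-data generators with
    embedded ground truth for every input class, enabling
    parameter-recovery validation of each analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
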