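Package: modularMEA
Title: Network Activity Analysis for Modular Two-Chamber MEA Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of multielectrode-array (MEA) recordings from modular
    neuronal cultures grown in two chambers (Source and Target) joined by
    instrumented microchannels. Provides median-based threshold spike
    detection on raw voltage traces, module-level network-burst detection,
    burst-propagation direction and probability estimation from peak-rate
    delays, post-stimulus time histogram (PSTH) quantification of evoked
    responses, and classification of tetanus-induced potentiation or
    depression. Includes a seeded statistical simulator of the two-module
    network (spontaneous bursts, unidirectional propagation, evoked
    responses, raw-trace synthesis) that supplies ground truth for
    validating every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'burst-detect.R'
    'io.R'
    'layout.R'
    'modularMEA-package.R'
    'pipeline.R'
    'propagation.R'
    'simulate.R'
    'spike-detect.R'
    'stim-response.R'
    'utils.R'
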