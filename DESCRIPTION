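Package: GaitEnv
Title: Walking-Environment Classification from Stance-Phase Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for classifying the walking environment (flat
    ground, upstairs, downstairs, uphill, downhill) from lower-limb
    surface electromyography recorded during the stance phase of gait.
    Provides stance-phase segmentation from the vertical ground reaction
    force, linear-envelope extraction (band-pass, full-wave rectification,
    low-pass), flat-ground-peak amplitude normalization, time
    normalization of stance envelopes onto a 1000-point grid, a
    single-hidden-layer neural-network classifier trained with Adam on
    softmax cross-entropy, confusion-matrix evaluation (accuracy,
    one-vs-rest sensitivity and specificity), and a synthetic gait-signal
    generator that emulates environment-dependent muscle activation for
    eleven lower-limb muscles so the whole pipeline is testable without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    data.table,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
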