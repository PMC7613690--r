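Package: aistrack
Title: Tracking Axon Initial Segment Plasticity in Simulated HD-MEA Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Biophysical simulation and analysis toolkit for detecting and
    quantifying distal relocation of the axon initial segment (AIS) from
    extracellular high-density microelectrode array (HD-MEA) footprints.
    Provides multi-compartment neuron models (ball-and-stick, procedurally
    generated detailed morphologies, SWC import) with Hodgkin-Huxley-style
    sodium, delayed-rectifier potassium and Kv7 conductances, a compiled
    implicit cable-equation solver, a line/point-source volume-conductor
    forward model for planar electrode grids, spike-footprint feature
    extraction, neighborhood components analysis (NCA) feature selection,
    random-forest relocation detectors and wide neural-network magnitude
    regressors, and a linear-time-invariant kernel-library method that
    estimates AIS position without per-neuron morphological information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
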