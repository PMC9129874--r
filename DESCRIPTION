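Package: gluSynapse
Title: Single-Synapse Glutamate Imaging: Simulation, Event Detection, FRAP
    and Spatial Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of iGluSnFR single-synapse fluorescence imaging.
    Detects quantal evoked and spontaneous glutamate-release events in
    50 Hz ROI traces with a moving-baseline robust threshold, estimates
    release probability by failure analysis, fits fluorescence recovery
    after photobleaching (FRAP) curves by double normalization and
    single-exponential least squares, models use-dependent photobleaching
    of membrane probe pools with distinct lateral-exchange time constants,
    and quantifies probe clustering in localization point patterns with
    DBSCAN and a center-referenced pair-correlation function. A
    synthetic-data generator with exact ground truth (Bernoulli evoked
    release, Poisson spontaneous release, Gaussian point-spread movies,
    FRAP triplets, Thomas-process point fields) makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
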