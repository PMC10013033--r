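Package: dnmcrit
Title: Dynamical Network Marker Criticality Analysis of Event-Related EEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting critical slowing down in multichannel
    event-related EEG recordings via dynamical network markers (DNM).
    Provides a simulator of near-bifurcation linear network dynamics under
    an auditory oddball paradigm, epoch extraction and corrected-epoch
    construction (deviant minus mean standard response), mismatch-negativity
    (MMN) measurement, data-driven selection of the leading DNM subnetwork
    from group contrasts of fluctuation and correlation, criticality metrics
    (DNM index, distribution and network entropy of lagged Gaussian mutual
    information, conditional transfer entropy), and an epoch-ensemble
    psychosis-risk score with cohort risk-accuracy indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
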