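Package: fishvr
Title: Virtual-Reality Avoidance Learning Analysis for Zebrafish Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for closed-loop virtual-reality active/passive
    avoidance experiments with simultaneous two-photon calcium imaging in
    adult zebrafish. Provides a synthetic-data generator with known ground
    truth (trial schedules, tail-beat-driven behavior, ensemble-structured
    fluorescence, raw movies); rigid FFT registration, peaky-ness based ROI
    detection and dF/F0 extraction; template matching and non-negative matrix
    factorization with AIC order selection for neural-ensemble discovery; a
    flow-chart classifier for blue-perception, color-rule and scenery-flow
    prediction-error (SFPE) ensembles with a pairwise-swap shuffle control;
    correlation-versus-distance and permutation statistics; and a rate-coding
    plasticity simulator contrasting reward-prediction-error learning with
    and without an SFPE signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
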