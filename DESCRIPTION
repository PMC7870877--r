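Package: pvload
Title: Pressure-Volume Loop Analysis Under Acute Load Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of left-ventricular pressure-volume recordings under
    acute preload and afterload interventions: R-wave beat segmentation,
    extrasystole exclusion, conductance-catheter volume calibration,
    iterative slack-volume (Vd) estimation with maximal-elastance
    end-systole detection, linear and bilinear end-systolic pressure-volume
    relationship (ESPVR) fitting with geometric-mean-r2 breakpoint search,
    preload recruitable stroke work, and per-phase hemodynamic indices.
    Includes a closed-loop time-varying-elastance simulator (three-element
    Windkessel afterload, venous reservoir) that implements shortening
    deactivation as an afterload-dependent V0 shift and the Frank-Starling
    mechanism as beat-to-beat preload adaptation, producing ground-truth
    annotated synthetic recordings of the three load protocols for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
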