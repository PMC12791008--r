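Package: morphaline
Title: Morphodynamic Timeline Registration and Tissue-Flow Analysis
Version: 0.1.0
Authors@R:
    person("Morphaline", "Developers", email = "morphaline@example.org",
           role = c("aut", "cre"))
Description: Aligns time-lapse recordings of developing tissue onto a common
    morphological timeline by monotone time warping (weighted shortest paths
    through frame-similarity matrices), timestamps static snapshots onto that
    timeline with chi-squared-curvature uncertainties, and analyses tissue
    kinematics: minimal particle image velocimetry, Runge-Kutta pathline
    integration, velocity-field autocorrelation and stationary flow-module
    segmentation, temperature rescaling of kinematic curves, mitotic-clock
    ratios, and stripe-pattern decorrelation timescales. A companion module
    extends the correlation machinery to deforming triangulated surfaces
    (iterative closest point registration, mean-curvature times normal-velocity
    deformation fields, Lagrangian autocorrelation). Ground-truthed synthetic
    generators make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
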