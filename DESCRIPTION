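Package: twincpm
Title: Twin-Based Connectome Predictive Modelling of General Intelligence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A cross-twin connectome-based predictive modelling pipeline for
    resting-state functional connectivity (FC). Builds Fisher-z FC matrices
    from ROI time series, vectorizes their lower triangle into edge vectors,
    predicts general-intelligence (G) scores across co-twins with partial
    least squares regression under a leave-one-group-out twin split with
    bootstrap and permutation inference, extracts consensus edges and node
    connectivity strengths, performs co-twin fingerprint identification,
    predicts within-pair G-score differences from FC differences
    (whole-brain and per network), and provides twin and correlation
    statistics (Falconer heritability, Fisher z comparison of independent
    correlations, Cohen's q, Zou confidence intervals, power). A synthetic
    twin-cohort generator with known ground truth supports testing and
    calibration without access to restricted family data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
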