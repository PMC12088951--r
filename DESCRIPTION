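Package: facme
Title: Focal Adhesion Protein Turnover from FRAP and FLAP Curves via a
    Chemical Master Equation Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits single-exponential recovery and loss curves from
    fluorescence recovery after photobleaching (FRAP) and fluorescence
    loss after photobleaching (FLAP) experiments, and inverts the fitted
    turnover rate and stationary mobile fraction into protein entry and
    exit rates for a region of interest using the closed-form solution of
    a one-dimensional birth-death chemical master equation. Includes
    replicate outlier removal by interquartile-range fences, repeated
    K-fold cross-validation scored by mean absolute percentage error,
    first-order uncertainty propagation, a Gillespie stochastic
    simulator for protein-interaction perturbations (partner loss and
    gain couplings) with mean-field oracles, and a synthetic-trace
    generator with known ground-truth rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
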