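Package: cyclepop
Title: Bilateral Motor Cortex Population Analysis for a Unimanual Cycling Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis of bilateral motor-cortex population
    recordings collected while one arm performs a rhythmic cycling movement.
    Provides an inhomogeneous-Poisson session simulator with controllable
    lateralization and controllable overlap between the left-arm and
    right-arm population subspaces; spike-train smoothing and position-based
    trial alignment onto a canonical 2 Hz time base; single-unit
    lateralization statistics (modulation, arm-preference index, response
    correlations with shuffle nulls, a median-speed-split randomization
    test, Fano factor); population-geometry analyses (soft normalization,
    per-condition PCA subspaces, cross-arm variance capture, trajectory
    tangling); and reduced-rank linear decoding of muscle activity with
    cross-hemisphere comparisons and wrong-arm generalization tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
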