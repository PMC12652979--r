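Package: erswitch
Title: Bistable Switch Dynamics of the ER Stress Decision Network
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation model of the endoplasmic-reticulum
    stress decision network, in which an unfolded-protein-response (UPR) sensor
    inactivates BCL-2 and thereby releases mutually antagonistic autophagy and
    apoptosis inducers. The package simulates time courses under treatment
    schedules for the common ER stressors (tunicamycin, thapsigargin,
    dithiothreitol) with washout, escalation and autophagy-inducer rescue
    events; locates and classifies all steady states; computes balance curves
    (nullclines) of the quasi-steady-state-reduced autophagy/apoptosis plane;
    traces one-parameter bifurcation diagrams in the stress level with
    saddle-node detection; and runs seeded parameter-perturbation ensembles to
    assess robustness of the qualitative outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
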