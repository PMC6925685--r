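Package: locfuse
Title: Consensus Prediction of Bacterial Protein Subcellular
    Localization by Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fuses the score outputs of multiple bacterial protein
    subcellular localization predictors into a single consensus call.
    Fusion weights (per predictor, or per predictor and compartment)
    are learned by a particle swarm optimizer with time-varying
    acceleration coefficients and linearly decaying inertia, so that
    the weighted-sum argmax decision maximizes training accuracy.
    Includes majority-vote and average-probability-vote baselines, a
    committee-ablation protocol, a brute-force lattice oracle for
    validating the optimizer, and a synthetic-committee generator with
    controllable per-class confusion structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
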