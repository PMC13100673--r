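Package: tmsmap
Title: Regression-Based TMS Motor Cortex Mapping with Neuronal Response
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Localizes the cortical origin of motor-evoked potentials (MEPs)
    from transcranial magnetic stimulation (TMS) experiments with random
    coil placements, by per-element sigmoidal regression of MEP amplitudes
    on simulated electric-field quantities. Implements and compares three
    neuronal response models: the field magnitude |E|, the normal component
    |E-perp| (cortical column cosine model), and an effective field E-eff
    that rescales |E| by an orientation- and gradient-dependent normalized
    firing threshold from a look-up table. Includes layered cortical surface
    geometry with geodesic distances, a synthetic gyral phantom and
    figure-of-eight primary-field generator for end-to-end testing,
    pulse-subsampling convergence analysis (NRMSD and hotspot geodesic
    distance), exhaustive coil-placement optimization with shifted control
    placements, and mixed-model statistics for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    knitr
Config/testthat/edition: 3
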