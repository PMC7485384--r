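Package: standreflex
Title: Reflex-Based Balance Control of a Musculoskeletal Model in Perturbed Standing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward-dynamic simulation and identification pipeline for
    perturbed standing balance. A sagittal-plane musculoskeletal model with
    seven segments and nine Hill-type muscles per leg stands on a translating
    platform and is controlled by delayed proprioceptive reflexes (muscle
    spindle length feedback and Golgi tendon organ force feedback) that are
    gated by a dead zone on the whole-body centre of mass. Controller
    parameters are identified by effort-minimizing lexicographic particle
    swarm optimization under upright-stance constraints, and simulated joint
    angles and moments are compared against experimental (or synthetic)
    trajectories by Pearson correlation. Includes a random square-pulse
    platform perturbation generator and a synthetic pseudo-experiment
    generator so the full pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
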