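Package: posturesim
Title: Muscle-Driven Standing-Balance Simulation with Delayed
    Proportional-Derivative Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-dynamics simulation of human standing balance against
    multidirectional support-surface translations.  A rigid multi-link body
    driven by Hill-type muscle-tendon actuators is controlled by a neural
    controller combining constant feed-forward muscle activations with
    delayed proportional-derivative feedback on musculotendon length and
    lengthening velocity, passed through first-order activation dynamics.
    Includes the two-stage parameter-adjustment procedure (feed-forward
    candidates from zero-delay runs, then CMA-ES optimization of grouped
    feedback gains per perturbation direction), directional muscle-response
    profiling with cosine-similarity null testing, and passive ankle
    stiffness estimation by least-squares torque-angle regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
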