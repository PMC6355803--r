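Package: trunkcoord
Title: Forward-Dynamic Trunk Model for Axial Thorax-Pelvis Coordination in Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates apparent axial trunk stiffness and damping from gait
    kinematics with a single degree-of-freedom forward-dynamic model of the
    thorax driven by pelvis rotation and arm-swing moment, quantifies
    thorax-pelvis coordination as frequency-response phase and gain at the
    stride frequency, simulates the effect of manipulated stiffness and
    arm-swing moment on coordination, cross-validates stiffness against an
    inverse-dynamics moment-angle regression, and provides cohort-level
    statistics plus a synthetic gait-cohort generator with known ground
    truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
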