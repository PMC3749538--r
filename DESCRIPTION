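Package: spinesim
Title: Multibody Simulation of Scoliosis Correction Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parametric multibody model of the osteoligamentous T1-L5
    spine with rigid vertebrae, lumped six-degree-of-freedom elastic
    intervertebral discs and tension-only ligaments, instrumented with
    pedicle screws and a shaped rod. Simulates staged surgical correction
    of scoliosis (segmental translation followed by rod derotation) as a
    sequence of quasi-static equilibria found by energy minimization, and
    reports Cobb-angle trajectories, intervertebral disc stresses and
    screw pullout forces, with calibration of disc stiffness against
    lateral-bending flexibility tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
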