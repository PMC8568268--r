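Package: blindspotr
Title: Psychophysical Mapping of the Human Blind Spot with Simulated Observers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free implementation of a psychophysical blind spot
    assessment procedure: three-step moving-probe border point detection,
    transformed 1-up-3-down staircase refinement of border points toward a
    known visibility level, perimetric heat-map and scaling-ellipse
    validation, and standard-distance precision statistics. A parameterized
    simulated observer with an elliptical scotoma, boundary blur, lapse and
    guess rates, and fixation jitter replaces the human observer and
    eye-tracker, so complete mapping sessions can be run, tested, and used
    for parameter-recovery studies entirely in software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
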