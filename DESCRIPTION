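Package: gazecal
Title: Calibration and Evaluation of Smartphone Gaze Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating appearance-based smartphone eye tracking
    against fixed on-screen fixation tasks. Provides the four-task protocol
    geometry (calibration grid, two face layouts, circle trace), a
    moment-matching linear calibration that corrects per-subject shift and
    scale in gaze estimates, a support-vector-regression comparator, nearest
    facial-landmark misclassification and circle-trace error metrics, a
    normality-gated paired testing protocol with a Levene variance
    comparison, and a seed-reproducible synthetic gaze-estimate generator
    emulating per-subject biased predictions with blink and face-detection
    dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
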