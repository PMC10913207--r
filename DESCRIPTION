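Package: adaptivePI
Title: Dynamical Compensation and P-Invariance in Adaptive Proportional-Integral Feedback Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing dynamical compensation (DC) and P-invariance
    in a two-state adaptive proportional-integral feedback model of hormonal
    regulation. Provides the model right-hand sides (including the
    three-state hormonal circuit it simplifies), closed-form equilibria,
    Jacobians, eigenvalues and stability classification, seeded
    piecewise-constant step/noise input schedules, numerical integration with
    breakpoint-aware restarts, phase portraits, equivariance-based
    P-invariance verification, DC state rescalings, and paired-simulation
    output-invariance experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
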