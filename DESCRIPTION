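Package: graphomotor
Title: Bayesian Perception and Production of Cursive Letters
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A generative Bayesian model of single-stroke cursive
    handwriting in which letters are represented as sequences of
    via-points placed where the horizontal or vertical pen velocity
    vanishes.  Letter knowledge is stored as Laplace-smoothed first-order
    Markov tables over discretized via-points, trajectories are produced
    through minimum-acceleration (cubic Hermite) segments and executed by
    a simulated two-joint arm, and the same representation supports
    letter recognition, writer recognition, writing, copying, and
    recognition aided by internal motor simulation.  Includes a seeded
    synthetic-writer corpus generator and cross-validated evaluation
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
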