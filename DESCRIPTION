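Package: armioc
Title: Inverse Optimal Control Quantification of Arm Flexion Motor Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the penalty weights of a linear-quadratic-regulator cost
    functional to recorded wrist trajectories of a planar three-link arm
    performing shoulder flexion against gravity, and analyses the resulting
    controller. Includes the three-link arm dynamics with a smooth joint-limit
    constraint, a continuous algebraic Riccati solver, a Nelder-Mead inverse
    optimal control estimator of the angle and velocity penalties, principal
    velocity-resistance (gain partition) analysis, sinusoidal state
    perturbation with Wigner-Ville time-frequency energy summaries, a
    motion-capture skeleton CSV reader with Fourier resampling and planar
    angle extraction, a synthetic recording generator with known ground-truth
    weights, and Welch group comparisons of fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    signal,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
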