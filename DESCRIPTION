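Package: stsnorm
Title: Joint-Torque-Based EMG Normalization and Muscle Synergy Analysis for Sit-to-Stand
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normalizes surface EMG recorded during sit-to-stand movement without
    maximum-voluntary-contraction reference measurements. Joint torques are computed
    from a four-link sagittal-plane skeletal model by inverse dynamics; a Hill-type
    musculoskeletal model with 11 uni- and bi-articular muscles simulates the same
    torques from EMG-driven activations; per-muscle positive scale factors are found
    by constrained optimization so the simulated torque extrema match the
    inverse-dynamics torques while the normalized activation stays perfectly
    positively correlated with the measured envelope. Downstream analyses cover
    muscle-tension estimation, muscle-synergy extraction by non-negative matrix
    factorization, and longitudinal nonparametric comparison of rehabilitation
    features. Includes a synthetic sit-to-stand trial generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    kernlab,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
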