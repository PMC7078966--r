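Package: civrank
Title: Probabilistic Treatment Ranking in Network Meta-Analysis with
    Clinically Important Values
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranking metrics for network meta-analysis (NMA) summary
    estimates: analytic P-scores, simulation-based rankograms and SUCRA,
    P-scores conditioned on a minimum clinically important value (CIV),
    joint multi-outcome P-scores under an assumed between-outcome
    correlation, and benefit-risk curves over grids of harm tolerances.
    Operates on per-outcome relative effects versus a reference treatment
    with their covariance matrix, or on league tables of all pairwise
    effects with standard errors. Includes a synthetic-network generator
    with known ground truth and Monte-Carlo oracles for validation, and a
    command-line pipeline for CSV/JSON workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    mvtnorm,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
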