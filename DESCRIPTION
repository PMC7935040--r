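Package: connectrl
Title: Network Controllability of Structural Connectomes and Its
    Gray-Matter Correlates
Version: 0.1.0
Authors@R:
    person("Connectome", "Control Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes linear network control metrics (average and modal
    controllability, Kalman rank) from weighted structural connectomes,
    links them to regional gray-matter volume through linear mixed-effects
    interaction models with a participant random intercept, and tests the
    gray-matter effect against degree-preserving randomized null networks.
    Includes proportional thresholding of streamline-count matrices, a
    fully seeded synthetic cohort generator with known ground truth, and a
    config-driven pipeline runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
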