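Package: neofinger
Title: Connectome Fingerprinting for Longitudinal Neonatal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for test-retest connectome fingerprinting in developing
    cohorts scanned at two timepoints. Builds Pearson and partial-correlation
    functional connectivity from ROI timeseries, applies proportional network
    density thresholding with timepoint-1 edge masks, computes Spearman
    similarity matrices and identifiability rates (globally and within
    anatomical clusters), and models age and inter-scan-interval effects on
    self- and self-to-other-similarity with linear and mixed-effects models.
    Includes a seeded synthetic cohort generator with tunable fingerprint
    strength, developmental drift and noise for method validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
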