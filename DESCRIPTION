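Package: pxscan
Title: Exposure-Wide Association Scans and Polyexposure Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exposome-wide association studies (XWAS) and for
    deriving, calibrating and validating polyexposure risk scores (PXS)
    from cohort data with continuous, binary or censored survival
    outcomes.  Exposure selection uses cross-validated elastic-net
    (lasso by default) regression followed by backward stepwise
    calibration, or hierarchical group-lasso selection of pairwise
    exposure interactions under a strong-hierarchy guarantee.  Includes
    paired-bootstrap comparison of model goodness of fit (R-squared,
    AUC, Harrell's C-index), top-decile risk stratification, a seeded
    synthetic-cohort generator with known ground truth, plotting of
    scan results, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
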