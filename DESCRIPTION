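Package: youdenci
Title: Wilson Square-and-Add Confidence Intervals for the Youden Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Point estimation and confidence intervals for the Youden Index
    of a diagnostic test with continuous or ordinal endpoints, from two-group
    (non-diseased/diseased) data.  Implements the empirical and
    Agresti-Coull-adjusted cut-point estimators, two score-type intervals
    obtained by combining Wilson limits for the component proportions with
    the square-and-add (MOVER) method (the NP and NPAC intervals), and the
    bootstrap mean-and-variance comparator based on the adjusted estimate
    (the BAC interval).  Also provides exact computation of the true Youden
    Index for parametric scenarios (normal, gamma, Student-t), calibration
    of a scenario parameter to a target index, and a Monte-Carlo engine for
    coverage-probability and average-width studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
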