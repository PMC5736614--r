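Package: feedlearn
Title: Feedback-Learning Task Simulation and Longitudinal Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-stimulus feedback-learning (sorting) task and
    win-stay/lose-shift agents, classifies every feedback event by informative
    value and valence (learning vs. application phase), and computes the
    learning-performance statistic. Generates synthetic accelerated-longitudinal
    cohorts of region-of-interest fMRI contrast values with known ground truth,
    and provides the developmental-trajectory machinery used to analyse them:
    random-intercept mixed models with a no-age/linear/quadratic age ladder
    compared by AIC and likelihood-ratio tests, predicted trajectories with
    confidence bands, peak-age estimation with bootstrap intervals, intra-class
    correlation, residualized brain-behavior hierarchical regressions, lagged
    cross-wave prediction, and a Bonferroni correction adjusted for correlated
    variables via the effective number of tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
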