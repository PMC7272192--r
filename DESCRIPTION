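Package: memupdate
Title: Simulation and Multivariate Analysis of Memory-Updating Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying memory updating in three-day A-B/A-C
    retrieval-practice paradigms with multivariate pattern analysis. Generates
    complete synthetic experiments (pair assignments, IRI-constrained trial
    schedules, category-templated voxel patterns, behavioral responses) with
    known ground truth; implements the three-stage normalization cascade and
    phase-specific TR pooling; trains one-vs-rest L2-regularized logistic
    category classifiers and reassigns their outputs to target, competitor and
    'other' reactivation evidence; fits nonmonotonic-plasticity (U-shaped)
    curves by importance sampling over three-segment piecewise-linear curves
    with a permutation test; and links ROI activation to representational
    change with random-intercept mixed models compared by likelihood-ratio
    tests. Includes behavioral scoring, within-subject error bars,
    repeated-measures ANOVA for two-level designs, and FDR correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
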