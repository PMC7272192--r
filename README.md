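# memupdate

Simulation and multivariate analysis of memory-updating experiments.

## The problem

In an A-B/A-C updating paradigm, an over-trained association between a cue
word (A) and a picture (B) must be replaced by a new association with a
picture from a different visual category (C), either by repeated cued recall
with feedback (retrieval practice, *RetPrac*) or by passive re-exposure
(*Restudy*). Multivariate pattern analysis of fMRI data makes the hidden
competition observable: category classifiers trained on an independent
localizer are applied to updating and final-test trials, and their output
probabilities are reassigned per trial to

* **target evidence** — probability of picture C's category,
* **competitor evidence** — probability of picture B's category,
* **"other" evidence** — probability of the remaining category,

with normalized evidence `target_norm = target_ev - other_ev` and
`competitor_norm = competitor_ev - other_ev`.

`memupdate` implements this analysis chain for R, along with the two
model-based stages built on top of it:

* **Nonmonotonic plasticity curve fitting** — a Bayesian importance-sampling
  fit of three-segment piecewise-linear curves relating competitor
  reactivation during updating (normalized to [0, 1]) to its later change,
  reporting the posterior probability that the curve is theory-consistent
  (U-shaped: moderate reactivation weakens a memory, strong reactivation
  strengthens it; chance level 0.5 by construction), with a permutation test.
* **Activation-evidence linkage** — random-intercept mixed models
  (`outcome ~ predictor + (1 | subject)`) compared against their null by a
  maximum-likelihood likelihood-ratio test (chi-square, 1 df).

Because the original subject data cannot be redistributed, the package ships
a first-class synthetic-data generator that emulates the full three-day
paradigm — 144 pairs split 72/72 between conditions, 6 updating runs of 12
unique pairs per condition repeated 3 times with inter-repetition intervals
of 10–36 trial positions, a 3 x 48 final test, a 4-run localizer with 72
trials per category, category-templated voxel patterns, a behavioral response
model, and a known generative plasticity curve — so every stage is verifiable
by parameter recovery.

## Worked example

```r
library(memupdate)

report <- run_pipeline(experiment_config(), n_subjects = 19, seed = 7)
print(report)
#> memupdate pipeline report (seed 7, 19 subjects)
#>   decoder CV accuracy: mean 1.000 (range 1.000-1.000)
#>   updating competitor evidence RetPrac-Restudy: t(18) = 62.41, p = 1.7e-22
#>   P(theory consistent) = 0.001 (fit_failed)
#>   long-term linkage: chi2(1) = 1548.16, p = 0
#>   stages: decode=ok, aggregate=ok, pcit=ok, pcit_permutation=skipped, linkage=ok
```

Reading the output: leave-one-run-out decoding is at ceiling at the default
synthetic noise level; updating-phase competitor reactivation is higher under
RetPrac than Restudy (the generative condition difference, recovered with
t(18) = 62.4); and the linkage stage detects the generative coupling between
per-pair ROI activation and final-test target-minus-competitor evidence
(chi-square(1) = 1548). The plasticity stage pools ~1400 pairs across
subjects, which makes the Gaussian likelihood so peaked that the uniform
curve prior cannot populate the posterior (effective sample size < 50) — the
fit honestly reports `fit_failed` rather than an unstable number; fitting at
the single-dataset scale (n = 72) recovers generative curve shapes reliably,
e.g.:

```r
u <- default_plasticity_curve()          # U-shaped ground truth
set.seed(21)
x <- runif(72)
y <- curve_value(u, x) + rnorm(72, 0, 0.1)
fit <- pcit_fit(normalize_x(x), y, n_samples = 10000, seed = 1)
fit$p_theory_consistent
#> [1] 0.9999239   # theory-consistent; chance level is 0.5
pcit_permutation_test(x, y, n_perm = 1000, n_samples = 10000, seed = 2)$p_value
#> [1] 0.000999001
```

See `vignettes/memory-updating-pipeline.Rmd` for the model, the normalization
cascade, parameter defaults and their rationale, and known limitations.

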