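---
title: "Simulating and analysing memory updating with memupdate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing memory updating with memupdate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memupdate)
```

## The scientific problem

When an established association (a cue word A paired with picture B) must be
replaced by a new one (A paired with picture C from a different visual
category), the old memory competes with the new one. Multivariate pattern
analysis of fMRI data can track this competition: classifiers trained to
recognize the cortical signature of each picture category (face, object,
scene) are applied to updating and test trials, and their output probability
for the category of picture C is read as *target* reactivation, the
probability for the category of picture B as *competitor* reactivation, and
the probability for the remaining category as a within-trial baseline
("other" evidence).

`memupdate` implements this analysis chain end to end — classifier training,
evidence assignment, condition contrasts, nonmonotonic-plasticity curve
fitting, and activation-to-representation linkage — together with a
synthetic-data generator that emulates the three-day A-B/A-C retrieval
practice paradigm with a fully known ground truth. Every stage of the
analysis can therefore be validated by parameter recovery rather than by eye.

## The synthetic paradigm

`experiment_config()` describes the design. The defaults reproduce the study
conditions:

* 144 A-B/A-C triads, with B and C always from different categories, the six
  ordered category combinations filled evenly, and half of the pairs assigned
  to retrieval practice (RetPrac) and half to Restudy;
* 6 updating runs, each containing 12 unique pairs per condition, every pair
  shown 3 times with an inter-repetition interval (IRI) of 10–36 trial
  positions;
* a final test of 3 runs x 48 pairs covering every pair once;
* a localizer of 4 runs x 9 six-trial miniblocks (3 miniblocks per category
  per run), i.e. 72 trials per category for classifier training.

The IRI is interpreted as the difference in trial positions between
consecutive repetitions of a pair; with 72 trials per run this is the only
reading compatible with the run length. The scheduler places each pair once
per repetition sweep (three consecutive 24-trial blocks) and draws
within-block positions by randomized tightest-first matching until all gaps
fall inside the bounds, retrying a bounded number of times
(`max_schedule_retries`, default 1000) before raising an error that reports
the attempt count.

### Generative signal model

Voxel patterns are simulated at TR resolution (TR = 2 s). Each category has a
unit-norm template over `n_voxels` (default 120) with pairwise |cosine| below
0.2. The volumes inside a trial's pooling window carry the trial's signal —
`target_coef * template_C + competitor_coef * template_B` for updating and
test trials, the presented category's template for localizer trials — plus
i.i.d. Gaussian noise everywhere (`noise_sd`, default 0.12). There is no
hemodynamic convolution, drift, or autocorrelated noise: the generator
emulates the *pooled pattern* level at which the analysis operates, not raw
BOLD physics. Passing tests on these data therefore demonstrates the
correctness of the analysis chain, not robustness to realistic fMRI
artifacts.

The default `noise_sd = 0.12` was set so that decoding is reliable but not
trivial: with unit-norm templates and two-volume pooling the per-trial noise
projected onto a template direction is about 0.08 on the coefficient scale,
comfortably below the generative spread of the competitor coefficients
(conditional means 0.6 for RetPrac vs 0.15 for Restudy, sd 0.15, clipped at
zero). Note that even at zero noise, trial-level competitor evidence is an
imperfect readout of the generative coefficient: the across-voxel z-scoring
and the renormalization of the three classifier outputs couple the (varying)
target coefficient into the competitor channel. The conditional *mean* of
competitor evidence remains a cleanly increasing function of the coefficient,
which is what the recovery tests assert.

Ground truth couples the phases: test-phase competitor coefficients equal the
updating coefficient plus a generative plasticity curve (default: the
U-shaped `default_plasticity_curve()`) evaluated at the coefficient min-max
normalized across pairs, clipped at zero. When behavioral data are supplied,
updating target coefficients are raised by `subsequent_memory_boost`
(default 0.3) for pairs answered correctly at the final test, creating a
recoverable subsequent-memory effect. Synthetic per-pair ROI activations
(standing in for per-item GLM betas) are generated as
`intercept + coupling * (test target - test competitor coefficient) + noise`,
giving the linkage stage a known positive slope to detect.

### Behavioral model

Responses are drawn from per-condition multinomials over
{target, competitor, other, dontknow}; the defaults follow the qualitative
behavioral pattern of the paradigm: RetPrac retrieval starts near the 1/3
chance level at repetition 1 (0.35) and rises steeply (0.65, 0.85), Restudy
category judgments are correct with probability 0.99, and final-test
performance favors targets under RetPrac (0.55 vs 0.45) with more competitor
intrusions under Restudy (0.28 vs 0.20). The per-repetition multinomial is
deliberately the simplest structure matching that pattern — no latent
learning model is implied.

## The normalization cascade

The analysis normalizes each run in a fixed order: z-scoring of every voxel's
time series within a run, then z-scoring of every volume across voxels, then
trial pooling, then a final z-scoring of every voxel across all of a phase's
pooled trials. The sample standard deviation (denominator n-1) is used
throughout. Pooling windows are phase specific: final-test trials average
volumes 3–6 after onset with weights (0.35, 0.35, 0.15, 0.15); updating and
localizer trials average volumes 3–4. "Volume k after onset" counts 1-based
from the first volume acquired at or after the onset, so the windows
correspond to roughly 4–12 s (test) and 4–8 s (updating/localizer) after
onset at TR = 2 s, respecting hemodynamic lag.

One genuine ambiguity is whether the final z-scoring is applied to volumes
before within-trial averaging or to the pooled trial vectors. The package
defaults to z-scoring the pooled trial patterns (the operative equivalent:
both readings standardize each voxel over the same phase-specific set), and
exposes the other order via
`preprocess_phase(..., third_zscore = "before_pooling")`. An optional
TR-exclusion mask (for motion-scrubbed volumes in real data) drops masked
volumes from pooling windows, renormalizes the remaining weights, and errors
if a window empties.

## Decoding

One-vs-rest L2-regularized logistic classifiers (one per category) are
trained on the localizer patterns by minimizing
`0.5 * ||w||^2 + C * sum(log(1 + exp(-t * (Xw + b))))` with `C = 0.01` and an
unpenalized intercept; the problem is convex and solved by BFGS with analytic
gradients to a fixed tolerance, so retraining is bit-reproducible.
Classifier quality is assessed by leave-one-run-out cross-validation.

Each binary model contributes its positive-class probability; the three are
renormalized to sum to one within each trial (the unnormalized variant is
available via `renormalize = FALSE`). Argmax ties are broken by the fixed
category order — they have measure zero but must be deterministic. Chance
level for the three-category problem is 1/3; the behavioral task offers a
fourth "don't know" button, but decoding targets only the three picture
categories.

## Aggregation and group statistics

`score_response()` maps categorical responses to target/competitor/other
outcomes, with roles reversing between A-C and A-B tests.
`label_update_history()` classifies pairs as first-correct (FC),
later-correct (LC) or incorrect (IC); pairs correct at repetition 1 but wrong
later keep a separate `FC_lapse` label and are excluded from FC/LC/IC
analyses. `evidence_cells()` aggregates trial evidence to subject-by-cell
means and reports within-subject standard errors by subject-mean centering
with the cell-count bias correction (multiplying the per-cell SE of centered
values by sqrt(C/(C-1)) for C cells). Trials answered "don't know" or not
answered are excluded from evidence cells.

`paired_contrast()` reports the paired t statistic with df = n-1 and Cohen's
d computed from the standard deviation of the paired differences (one of
several possible d conventions; it is stated rather than hidden).
`rm_anova()` covers fully crossed within-subject designs with exactly two
levels per factor — all this analysis needs — by the exact identity between
each effect's F ratio and a one-sample t on per-subject contrast scores; with
two levels there is no sphericity to correct. `fdr_adjust()` is
Benjamini-Hochberg step-up. Both are validated against independent
implementations (base `aov()` with an `Error(subject)` stratum, and
`p.adjust`).

## Nonmonotonic plasticity curve fitting

The relation between competitor reactivation during updating (x, min-max
normalized to [0, 1] over the analysis set) and the relative change of
competitor evidence at the final test (y) is estimated by importance sampling
over three-segment piecewise-linear curves: interior x-knots are two sorted
uniforms on (0, 1), y-values i.i.d. uniform on [-1, 1]. Each sampled curve
receives a Gaussian importance weight `exp(-SSR / (2 * noise_scale^2))`
(`noise_scale` defaults to sd(y)); weights are computed in log space with
max-subtraction. The posterior probability of theory consistency is the
weight share of the U-shaped curves; the posterior mean curve and a weighted
5th–95th percentile band are reported on a 101-point grid, along with the
effective sample size (ESS) of the weights. An ESS below 50 is reported as a
fit failure (a status, not an exception): a strongly peaked posterior that
the uniform curve prior cannot populate is not trustworthy at the default
sample size.

A curve counts as theory-consistent (U-shaped) when, over the grid, its
minimum is attained strictly inside (0, 1), lies strictly below both endpoint
values, is negative, and the right-endpoint value is positive — weakening at
moderate reactivation, strengthening at strong reactivation. The raw uniform
prior yields about 29% consistent curves; curves are therefore sampled from a
balanced mixture (half from each class, by rejection) so that the chance
level of the posterior is exactly 0.5 by construction. The raw prior remains
available (`balanced = FALSE`).

Two independent validation routes are built in. First, on synthetic null
data (y independent of x) the mean posterior consistency is 0.5 within
Monte Carlo error. Second, `pcit_enumerate()` recomputes the posterior by
exhaustive enumeration over a dense lattice of curves (interior knots in
steps of 0.05, y-values in steps of 0.1) — a sampling-free oracle that agrees
with the importance sampler to within 0.02 on small instances.

A permutation test (default 1000 permutations) shuffles y against x and
recomputes the consistency posterior per shuffle with the same curve sample
(weights are recomputed per permutation; reusing the sample is a
common-random-numbers refit, valid because the sample is independent of the
y ordering), reporting `p = (1 + #{permuted >= observed}) / (n_perm + 1)`.

### A known limitation of the U-shape criterion

The consistency rule admits curves with an arbitrarily shallow, arbitrarily
narrow dip. For data generated from a monotone increasing relation that
spans both negative and positive values, curves with an "epsilon-dip"
squeezed between adjacent data points fit exactly as well as the best
monotone curve, so at very large curve-sample sizes the consistency posterior
for such data converges to roughly the balanced-prior chance level rather
than to zero. The posterior is decisively low for monotone relations whose
right end stays below zero (the strengthening arm, y(1) > 0, is then a
binding misfit) — the package's opposite-direction recovery checks use such a
curve (a weakening effect that fades with reactivation strength). Users
should read a consistency posterior near 0.5 as "not diagnostic", not as
evidence against monotonicity.

## Activation-evidence linkage

`build_suppression_table()` pairs each eligible pair's ROI activation at
repetition r with the drop in competitor evidence from r to r+1 (filtered to
FC or FC+IC pairs); `build_longterm_table()` pairs each pair's mean
activation across repetitions with final-test target-minus-competitor
evidence. `lmm_lrt()` compares `outcome ~ predictor + (1 | subject)` against
the intercept-only null. Both models are fitted by maximum likelihood rather
than REML: REML likelihoods are not comparable between models with different
fixed effects, so a valid likelihood-ratio test requires ML. Random slopes
are deliberately omitted (random intercepts only). Singular (boundary)
random-effect fits are retained and flagged; a numerically negative
likelihood-ratio statistic is clipped to zero. With a single subject the
model degrades to ordinary regression, with a warning. The LRT is invariant
under affine rescaling of the predictor, so predictors are not standardized
by default.

## The pipeline and its report

`run_pipeline()` runs generation, preprocessing, decoding, aggregation,
plasticity fitting, and linkage for `n_subjects` synthetic subjects (default
19) from one master seed fanned out to per-stage child seeds, so each stage
is individually reproducible and the whole report is deterministic given the
seed. Stages can be disabled and are then reported as "skipped"; a stage
failure is recorded in the report status rather than aborting the run.
`save_report()` writes the report as JSON plus TSV tables.

On the plasticity stage the pipeline pools pairs across subjects (about 1400
rows under the defaults). With that much data the Gaussian likelihood is
extremely peaked and the uniform curve prior cannot populate the posterior
region, so the ESS criterion typically reports "model fitting failed" — the
same failure mode the method exhibits on strongly informative data, surfaced
honestly in the report instead of being masked.

## Problem sizes used in the tests

Unit tests use a quarter-scale design (24 pairs, 2 updating runs, 40 voxels)
where full-scale structure is not the point. The acceptance checks use the
full default design: 60 null datasets of 72 points for the chance
calibration of the curve-fitting procedure (10,000 curve samples each); a
dense-lattice enumeration oracle on a 5-point instance; U-shaped and
monotone recovery at n = 72 with generative noise sd 0.1 and 1000
permutations; 2000 null simulations each for the ANOVA and mixed-model
type-I calibration; and a 19-subject end-to-end run for the directional
recovery of the generative condition and subsequent-memory effects.

## Limitations

* The generator works at the pooled-pattern level; no hemodynamics, drift,
  autocorrelation, or motion artifacts are simulated (a TR-exclusion mask is
  accepted but exercised only synthetically).
* Real-data ingestion expects pre-extracted ROI pattern matrices; raw BOLD
  preprocessing is out of scope.
* `rm_anova()` is restricted to 2-level within-subject factors.
* The plasticity fit's uniform curve prior limits the usable likelihood
  sharpness; very informative data produce low-ESS "failed" fits by design.
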