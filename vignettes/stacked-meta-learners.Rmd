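---
title: "Stacked meta-learners for clinical risk prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked meta-learners for clinical risk prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metastackr)
```

# The model

metastackr implements a stacked-generalization pipeline for tabular clinical
risk prediction with two outcomes per patient: an integer symptom-severity
score bounded to the PHQ-9 range 0–27 (continuous task) and an all-cause
treatment-dropout indicator (binary task). Two base-learners of deliberately
different families are fitted on the 31 baseline predictors, and their
out-of-sample predictions become the sole inputs of two meta-learners.

**Ridge with restricted cubic splines.** The statistical base-learner is an
L2-penalized regression. Each of the three continuous predictors (age, BMI,
baseline severity) enters through a restricted cubic spline basis with four
knots at the 5th/35th/65th/95th percentiles of the training values — the
Harrell convention. With $k$ knots the basis contributes $k-1$ columns: the
identity plus $k-2$ truncated-cubic combinations constrained to be linear
beyond the boundary knots, each divided by $(t_k-t_1)^2$ so all columns share
a comparable scale under the penalty. Categorical predictors enter as full
indicator blocks (the penalty absorbs the collinearity), binaries as-is.
The intercept is never penalized. For the continuous task the solution is
computed exactly through the SVD of the centered design, so the entire
penalty path — including $\lambda = 0$, which reproduces ordinary least
squares — is available without iterative error; the binary task maximizes
the penalized logistic likelihood by IRLS. Unless a penalty is fixed, it is
chosen by internal 5-fold cross-validation over 25 log-spaced values in
$10^{-4}\dots10^{4}$.

**Multi-layer perceptron.** The machine-learning base-learner is a fully
connected network with three hidden layers of 256 rectified-linear units
(`mlp_control()` defaults), squared-error loss for the continuous task and
sigmoid cross-entropy for the binary task. The network is implemented in the
package with plain matrix arithmetic. Training details are conventional and
stated explicitly so results are reproducible: He-normal initialization,
the adaptive-moment (Adam) optimizer at step size $10^{-3}$, mini-batches of
256, up to 100 epochs with early stopping (patience 10) on a 10% internal
validation split, inputs standardized with training-set parameters. Training
is deterministic given the seed. Width, depth and epochs are exposed in
`mlp_control()`; scaled-down studies in this package configure them
explicitly rather than silently.

**Out-of-sample stacking.** Training a meta-learner on in-sample base
predictions would reward overfitted base-learners. The pipeline therefore
draws, within each of the $m$ imputed datasets, $B$ bootstrap samples of
size $n$ (with replacement; defaults $m=10$, $B=20$, hence 200 fits per
learner), fits both base-learners on each bootstrap sample, and predicts
only on that sample's out-of-bag complement. A bootstrap sample contains on
average a fraction $1-(1-1/n)^n \to 1-1/e \approx 63.2\%$ of distinct
patients, leaving ~36.8% out-of-bag each time. Per-patient predictions are
averaged across all replicates and imputations in which the patient was
out-of-bag, giving exactly one prediction per base-learner per
outcome-observed patient. This single pooling across both levels is a
deliberate design choice; the package asserts structurally (`audit_oob()`)
that no contribution ever comes from a model whose training multiset
contained that patient. Patients never out-of-bag — probability
$(1-1/e)^{mB}$, negligible at the defaults — are excluded from meta-training
with a warning rather than refitted, preserving the leakage guarantee.

**Meta-learners.** The first is an intentionally unregularized linear
(continuous) or maximum-likelihood logistic (binary) regression on the two
averaged prediction columns plus an intercept. Because no penalty may be
added, a rank-deficient design (e.g. perfectly collinear base predictions)
falls back to the minimum-norm solution — pseudo-inverse least squares, or
IRLS whose Newton steps use the pseudo-inverse so null-space components stay
at zero — with a warning. A useful consequence of the logistic score
equations is exact training-set calibration-in-the-large: the mean predicted
probability equals the observed event rate. The second meta-learner is an
MLP of the same architecture as the base network. An optional covariate
augmentation path appends (imputed) patient covariates to the meta inputs.

# Missing data

Predictor missingness is handled by chained-equations multiple imputation
implemented in the package: each incomplete variable is regressed on all
other predictors *and both outcomes*, with spline-flagged continuous
predictors entering the conditional models through the same 4-knot basis as
the analysis model. Continuous variables are drawn by predictive-mean
matching (donor pool 5), binary and categorical variables from predicted
class probabilities (logistic / multinomial). Five burn-in cycles are run
per copy; copy $j$ draws from stream `seed + j`. The continuous outcome
participates in the chain so that it can inform predictor imputation, but
returned datasets restore its original missingness pattern: a patient with
an unobserved outcome never contributes an imputed outcome to model fitting
or evaluation (`outcome_availability_mask()`). Iteration count and draw rule
are stated here as the package's own defaults because the upstream
methodology they follow leaves them open.

# Evaluation protocol

*Base-learners*: the per-plan out-of-bag MAE / AUC / calibration values (one
per bootstrap replicate per imputation, $m \times B$ in total) are averaged
for the point estimate; the 2.5th–97.5th percentiles of the same values give
the interval. *Meta-learners*: the meta-feature rows are resampled with
replacement $R = 200$ times; each resample refits both meta-learners and
scores them on its out-of-bag complement. The quantile convention is fixed
to linear interpolation (`stats::quantile` type 7) so interval endpoints are
bit-reproducible. MAE comparisons are plain relative changes; AUC
comparisons first subtract the 0.5 chance baseline — mixing the two
conventions is intentional and matches how this literature reports both
metrics. Note that percent changes computed from 2-decimal rounded estimates
(e.g. +2.38% from 4.63 → 4.52) differ slightly from those computed on
unrounded estimates.

*Permutation importance*: 10 of the trained bootstrap models per learner are
sampled (seeded, without replacement); each predictor of each model's own
out-of-bag data is shuffled 100 times; the percent change in the model's
metric (MAE increase, AUC decrease, both oriented so larger = more
important, AUC unadjusted) is averaged over shuffles, then over models —
the mean-of-per-model-percent-changes orientation is a package decision
where the protocol leaves the order open. Because every design transform is
row-wise and frozen, the implementation permutes the feature's design-matrix
block directly, which is exactly equivalent to shuffling the raw column and
rebuilding, at a fraction of the cost.

*Internal–external cross-validation*: one region at a time is held out; the
remaining nine regions develop everything — imputation models, knots,
preprocessing parameters, base-learners, meta-learners. The held-out
region's missing predictors are completed by a single seeded draw from the
frozen training imputer, whose prediction-time conditional models use
predictors only (outcomes are unavailable when the model is deployed). For
test-side prediction the package refits one base-learner per imputed
training dataset on the full training fold and averages the $m$ predictions
per learner; these averages also serve as the meta-learners' test inputs.
The across-region summary is an unweighted mean. Both choices are package
decisions where the protocol text is silent. Fold frozen state is invariant
to arbitrary changes in the held-out region's data, and the test suite
asserts this bit-for-bit.

# The synthetic cohort generator

The motivating data — UK primary-care records of patients starting
fluoxetine — are access-restricted, so the generator reproduces the
*structure* the analysis assumes, with oracle ground truth for validation:

* 31 predictors: age ~ U(18, 90); BMI ~ N(27, 5²) clipped to 15–45;
  baseline severity ~ round(N(16, 5²)) clipped to 0–27; ethnicity
  (5 levels) and deprivation quintile; 26 Bernoulli comorbidity/history
  flags with marginals drawn once per seed from 0.05–0.40.
* Continuous outcome: linear predictor dominated by baseline severity
  (0.45 points per point, echoing its dominant importance in routine data),
  plus a smooth cubic bend in severity and a severity-by-age interaction
  (both scaled by config weights so purely linear and strongly nonlinear
  regimes are both reachable), a random region intercept
  (SD 0.3 — between-region heterogeneity is realistically small), and
  Gaussian noise (SD 5.5, chosen so model MAEs land in the mid-4s on the
  PHQ-9 scale, the regime the method targets); then rounded and clipped to
  0–27. The outcome is observed for 16384/187757 ≈ 8.7% of patients,
  mirroring the severity subcohort fraction.
* Binary outcome: logistic latent model led by ethnicity and deprivation,
  with the intercept solved numerically so the mean event probability
  equals the 37.5% target exactly.
* Missingness: missing-at-random by construction — masking probabilities
  depend only on fully observed drivers (age, sex); 75% for baseline
  severity, small rates elsewhere.

The oracle records each patient's latent mean (before and after clipping)
and true event probability, enabling recovery tests: calibration of the
oracle probabilities, the noiseless limit where the integer outcome equals
the rounded latent mean exactly, and imputation accuracy measured against
an oracle conditional-mean bound.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: realistic correlation among predictors (flags are
independent), coding artifacts and measurement error of routine records,
informative (MNAR) missingness, rating-scale conversions, or
treatment-discontinuation coding. Results on synthetic cohorts validate the
machinery and its qualitative behavior, not real-world effect sizes.

# Numerical choices and degenerate inputs

* Named seed streams: every stage (generation, missingness, each imputation
  copy, each bootstrap plan, each fit) derives its own sub-seed from the
  master seed, so inserting or re-running a stage never shifts another
  stage's draws; identical config + seed gives byte-identical output.
* Knot placement requires at least $k$ distinct values; constant or
  near-constant predictors raise a typed degenerate-predictor error. Ties in
  the quantiles fall back to quantiles of the distinct values.
* Ridge at $\lambda = 0$ on a rank-deficient design returns the minimum-norm
  least-squares solution (SVD with a relative singular-value cutoff of
  $10^{-10}$).
* Preprocessing modes (`none`, z-standardization, min–max normalization) are
  estimated on training rows only and frozen; a zero-variance column gets
  scale 1. The three modes are compared by `preprocess_sensitivity()`.
* AUC uses midranks, so tied scores count one half; an evaluation set with a
  single outcome class raises a typed error (and such IECV regions are
  skipped with a warning).
* Bounded outputs: binary predictions are probabilities by construction;
  continuous predictions are not clipped to 0–27, since MAE on the latent
  scale is the evaluation target.

# Problem sizes used by the shipped studies

The packaged tests and the acceptance script exercise the full protocol
counts (m = 10, B = 20, R = 200, 10 models × 100 shuffles) on small cohorts,
and the behavioral studies (stacking dominance, importance, IECV) on
cohorts of 2,000–5,000 patients with perceptrons explicitly configured to
32-unit layers and 25–40 epochs. These sizes are the package's chosen
desk-scale study conditions; the defaults remain the full-scale protocol.

# Known limitations

* The meta-learner uncertainty bootstrap (row resampling of the
  meta-feature table with out-of-bag scoring) treats the averaged features
  as fixed; it does not propagate base-learner refitting into the interval.
* Imputation pools predictions, not coefficients: no Rubin's-rules variance
  combination is attempted, and no MNAR sensitivity analysis is provided.
* The perceptron meta-learner needs hundreds of outcome-observed patients
  before it reliably matches the linear meta-learner (see the README
  example); on small severity subcohorts the linear combiner is the safer
  default.
* Only the two shipped base-learners are wired in; the stacking store is
  learner-keyed, so adding a third learner is mechanical but intentionally
  out of scope.
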