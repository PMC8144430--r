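---
title: "Prognostic modelling of negative-symptom outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prognostic modelling of negative-symptom outcomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the models and
procedures it implements, the assumptions behind them, the parameters that
matter, what the synthetic cohorts do and do not emulate, and the design
choices made where several defensible readings existed.

```{r setup, message = FALSE}
library(negsymprog)
```

## The prognostic problem

Individuals at clinical high risk (CHR) for psychosis frequently present
negative symptoms — social anhedonia, avolition, blunted emotional expression,
reduced experience of emotions, impaired occupational functioning — and these
symptoms predict later functional impairment. The pipeline forecasts, from
baseline data alone, whether a subject will show a *moderate/severe*
negative-symptom outcome at the 9-month follow-up, defined as any of the SIPS
negative-symptom items N1, N2, N3, N4, N6 rated ≥ 3 (0–6 scale). Item N5
(ideational richness) is excluded from both predictors and outcome because
factor-analytic work places it apart from the other negative-symptom items.
Global Functioning Social/Role scores (1–10) are dichotomized at the
conventional cutoff: > 7 adequate, ≤ 7 impaired.

Two baseline predictor views are supported: the five SIPS-N item ratings, and
cortical gyrification in the 68 Desikan–Killiany ROIs. Gyrification is a
surface-based folding measure thought to be sensitive to early
neurodevelopmental deviation, which motivates its use in the psychosis
high-risk state.

## Classification under leave-site-out nested cross-validation

`fit_lso()` trains a regularized linear classifier per outer fold:

* **Outer loop**: leave-site-out (LSO). Each recruitment site is held out once;
  models never see the held-out site during training or preprocessing. This
  estimates geographic generalizability to a hypothetical new centre — a more
  honest (and usually harsher) estimate than pooled k-fold when site batch
  effects exist.
* **Inner loop**: stratified 5-fold cross-validation repeated 10 times on the
  outer-training subjects selects the regularization strength λ from a
  log-spaced grid (default 10³…10⁻³, 7 values) by mean inner balanced
  accuracy. Ties resolve toward stronger regularization.
* **Ensembling**: all inner-loop models at the winning λ (50 members at the
  defaults) are retained; a held-out subject's decision score is the mean of
  the member scores, and the predicted label is score > 0. The alternative
  `ensemble = "refit"` refits a single model on the full outer-training set;
  averaging is the default because it propagates inner-loop variability into
  the weight profiles used for feature importance.

The classifier family is L2 logistic regression (via `glmnet`, ridge path)
with a linear hinge-loss SVM (`e1071`) as the alternative — both produce the
linear decision functions the importance machinery expects. The decision
threshold is fixed at 0 (probability 0.5); no operating-point tuning is done
anywhere, since the evaluation targets a single operating point.

Class imbalance (the default cohort has a 40 % positive rate) is handled by
inverse-prevalence sample weights, on by default.

**Preprocessing is strictly fold-local.** Each ensemble member stores its own
preprocessing estimated on its own training partition: the reference
intracranial volume (the training-mean ICV) for proportional ICV
normalization `roi * reference_icv / icv`, and per-feature z-standardization
(population-SD convention, divisor n). Test and external subjects are always
transformed with stored training parameters, never their own statistics.
Normalization by division rather than residualization is the simplest
reproducible reading of "normalized for intracranial volume"; both the
ordinal-item scaling and the ensembling rule are config-exposed
(`scale_items`, `ensemble`) rather than hard-coded, because the original
processing chain admits more than one reading.

**Stacking.** `fit_stacked()` uses the base models' out-of-site decision
scores as the two meta-features and trains the same linear family under the
same nested scheme. Provenance is asserted: a base score produced by a model
whose training partition contained that subject's site is a hard error.
A practical caveat the synthetic experiments make visible: site batch effects
do not only lower base-model accuracy, they also shift base-model *scores* by
site, so the meta-learner's training distribution differs from its test site;
under strong batch effects the stacked model can fall a few points below the
better base model on individual sites even when it helps on average.

## Evaluation: posterior balanced accuracy

Point metrics come from the pooled out-of-site confusion counts: SE, SP,
PPV, NPV, BAC = (SE+SP)/2, and the Mann–Whitney AUC (ties count ½). Pooling
across folds (rather than averaging per-fold metrics) matches reporting one
confusion matrix per model.

Inference on BAC is Bayesian: with a flat Beta(1, 1) prior (Jeffreys optional),
SE ~ Beta(TP+1, FN+1) and SP ~ Beta(TN+1, FP+1) independently, and the BAC
posterior is the distribution of their average — computed by numerical
convolution of the two Beta densities on a 4096-point grid (deterministic,
accurate to < 10⁻³ against 10⁶-draw Monte Carlo, which is also provided). The
credible interval is central/equal-tailed 95 %. A model is *significant* when
P(BAC > 0.5) ≥ 0.95. Under a true chance classifier with 50 subjects per
class this criterion fires in ~2–5 % of replicates (`exp_null_calibration()`
measures it), i.e. it is conservative at the nominal 5 %.

## CVR feature importance

For K fold-wise weight vectors w (all retained members across outer folds),
each vector is first normalized to unit Euclidean norm — making the profile
invariant to the arbitrary scale of each member's decision function — and per
feature CVR = mean(w)/SE(w), SE = sd/√K with the sample SD. CVR is therefore
√K times the one-sample t statistic of the normalized weights against zero
(a tested identity). Negative CVR means reduced predictor values accompany
increased risk. Features with zero SE across members are flagged and excluded
from ranking rather than reported as ±∞. Pooling across all members (rather
than per outer fold) is the default because it is the level at which the
ensemble actually operates; per-fold pooling can be had by calling
`cvr_profile()` on a single fold's weight rows.

## Sequential Bayesian risk stratification

`build_stratification_tree()` chains Bayes' rule through an ordered test
sequence, enumerating all 2^depth result paths:

* positive result: p → p·SE / (p·SE + (1−p)(1−SP))
* negative result: p → p(1−SE) / (p(1−SE) + (1−p)·SP)

Branch masses follow the law of total probability, so leaf masses sum to 1
and the mass-weighted leaf probabilities return the pretest exactly (asserted
to 10⁻¹²). Terminal probabilities are invariant to test order (likelihood
ratios commute); only the intermediate nodes differ. The canonical two-test
worked example — pretest 0.40, first test SE/SP 0.47/0.89, second 0.61/0.64 —
gives leaf probabilities 82.8 / 63.4 / 40.2 / 19.5 %:

```{r}
tree <- build_stratification_tree(
  0.40,
  list(diagnostic_test("SIPS-N", 0.47, 0.89),
       diagnostic_test("gyrification", 0.61, 0.64)),
  rr = 0.15)
tree
```

Two numerical caveats are deliberate. First, the (+,−) branch computes to
63.4 % from integer-percent inputs; a published value of 64 % for this branch
cannot be recovered exactly from rounded SE/SP, so the worked-example checks
assert that branch only within ±1 point. Second, risk categories follow the
published bins (high > 80 %, medium 40–64 %, low < 20 %) and the uncovered
gaps (20–40 %, 64–80 %) map to an explicit `indeterminate` category instead
of silently widening a bin.

**NNT.** For an intervention with risk ratio RR, the absolute risk reduction
in a group with outcome probability p is ARR = p(1−RR) and NNT = 1/ARR,
reported exact and nearest-integer rounded. RR is a required argument with no
default: it is a property of a specific intervention trial, not of this
pipeline. The value 0.15 used in examples back-solves the published NNT
ladder (1 / 2 / 3 / 6 across the four leaves above) and is a documented
reconstruction, not a measured quantity. Nearest-integer rounding (not
ceiling) is used because it is the only convention consistent with "NNT = 1"
at a leaf probability of 0.83.

`empirical_branch_rates()` computes the observed analogue: the outcome rate
among subjects on each result path, with empty paths flagged. Theoretical and
empirical rates agree only as far as the two tests are conditionally
independent given the outcome — the chaining assumption; correlated tests
make the theoretical tree over- or under-confident, which is why both are
reported.

## The synthetic cohort generator

No patient-level data are distributable, so `generate_cohort()` creates
cohorts with the dependence structure the analysis assumes:

* a standard-normal latent severity z per subject; baseline items are noisy
  copies of z cut into 7 ordinal bins (bin width 0.8 latent-SD, item noise SD
  0.8);
* a follow-up severity y = b·z + √(1−b²)·ε with b = `clinical_effect`
  (default 0.5); follow-up items are noisy copies of y (noise SD 0.6)
  thresholded so that P(any item ≥ 3) equals `target_prevalence` — the
  threshold is calibrated by numerical integration, so the realized prevalence
  is binomial around the target (0.40 for CHR, 0.59 ROP, 0.32 ROD, mirroring
  the cohorts being emulated). The binary label is then *derived from the
  items* by the labelling rule, never sampled directly, keeping items and
  label consistent;
* gyrification: per-region baseline levels (1.8–3.2, arbitrary but plausible
  positive values — the absolute scale is immaterial to the pipeline and no
  public per-ROI reference distribution was available), within-class noise SD
  0.15, additive per-site × per-ROI batch offsets with SD `site_sd` (default
  0.05), and `n_signal_rois` ROIs (default 8) shifted between outcome classes
  by `roi_effect` within-class SDs (default 0.8); 80 % of planted signs are
  negative, matching the predominance of risk-associated gyrification
  *reductions*. Raw stored values scale proportionally with the subject's
  ICV (lognormal around 1.5×10⁶ mm³, 8 % CV), which ICV normalization undoes;
* GF Social/Role follow-up scores derive from the same y with independent
  noise, so the functional-outcome generalization analysis has signal to find;
* the planted ROI identities and signs are returned as metadata, so
  importance-recovery tests need no re-inference.

Defaults for sizes (7 sites, 94 subjects CHR) and prevalences are the
emulated study conditions; `clinical_effect = 0.5` and
`roi_effect = 0.8` over 8 ROIs were chosen once to put base-model balanced
accuracies in the 60–85 % range where the method operates, and the
null generator (`generate_null_cohort()`) zeroes both effects while keeping
all marginals and site effects.

What the generator does **not** emulate: raw images or vertex-wise surfaces,
missing data, attrition, site differences in prevalence or rating behaviour,
item-specific factor structure beyond one latent, or correlated ROI noise
(beyond the shared site offsets and ICV factor). Passing recovery tests on
these cohorts therefore demonstrates the *machinery* — leakage-free CV,
calibration, importance recovery — not real-data effect sizes; published
real-data accuracies (60–76 %) are not reproduction targets here.

## Numerical and degenerate-input choices

* Zero-variance features are scaled by 1 with a warning, not dropped.
* Hyperparameter ties pick the larger λ (stronger regularization).
* Inner folds are stratified; a draw leaving a single-class inner training
  set is re-drawn, while a single-class *outer* training set is a hard error.
* `inner_k = 1` with a size-1 grid degenerates to one train/test split per
  site and is tested against a direct `glmnet` fit.
* PPV/NPV with empty denominators (a one-class predictor) are `NA` and
  flagged, not errors; empty classes in the truth are errors.
* The posterior grid uses midpoint discretization; the convolution index maps
  exactly onto the (SE+SP)/2 support, and FFT round-off is clipped at zero.
* All randomness (generator, fold draws, Monte Carlo) is seeded, and
  functions restore the caller's RNG state.

## Desk-scale experiment settings

The bundled experiments use 7 sites × 100 subjects and inner 5-fold × 3
repeats (instead of the 10-repeat default), sizes chosen so the full
recovery/calibration suite runs in a couple of minutes on one core while
leaving the measured quantities comfortably inside their tolerance bands:
`exp_stratification_worked_example()` (exact tree reproduction),
`exp_null_calibration()` (criterion firing rate on 200 null confusion
matrices; chance-level BAC on 10 null cohorts), and `exp_signal_recovery()`
(BAC ≥ 0.65 with posterior significance, ≥ 6/8 planted ROIs in the top-10
|CVR|, negative planted signs recovered, stacking within 2 points of the
better base, over 10 seeds).

## Known limitations

* The stratification chain assumes conditional independence of tests given
  the outcome; the SIPS-N and gyrification scores are correlated in practice,
  so theoretical PPVs are optimistic along concordant paths.
* The posterior-BAC construction treats SE and SP as independent Binomial
  rates, ignoring fold dependence in pooled counts.
* No site-harmonization (location-scale batch correction) is applied beyond
  what LSO-CV measures; that is a deliberate scope boundary, not an oversight.
* Linear models only; the weight-based CVR importance is undefined for
  non-linear families.
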