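---
title: "Methods: design and assumptions of the enwasr scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design and assumptions of the enwasr scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

An environment-wide association study (EnWAS) screens hundreds of
prenatal/perinatal exposures — questionnaire items, composite scales,
biomarkers — against one continuous child outcome, here the 18-item
short-form Social Responsiveness Scale (SRS), a parent rating of autistic
traits scored 0–3 per item. The statistical engine is deliberately simple
(one covariate-adjusted linear model per exposure); the scientific content
lies in the surrounding machinery: reproducible variable harmonization,
principled exclusion rules, split-sample multiple-testing control, and
sensitivity analyses. `enwasr` implements that machinery end to end and
ships a synthetic cohort generator so every stage is testable without
access to any restricted cohort data.

# The model

For exposure $j$ the package fits, by ordinary least squares,

$$ \sqrt{\bar{S}_i} = \beta_0 + \beta_j x_{ij} + \boldsymbol{\gamma}^\top
\mathbf{c}_i + \varepsilon_i $$

where $\bar{S}_i$ is subject $i$'s mean SRS item score over nonmissing
items and $\mathbf{c}_i$ the covariate vector. The square-root transform
addresses the strong right skew of $\bar S$. Exposure coding depends on
type:

* **continuous** — a single slope per unit;
* **ordered categorical** — consecutive integer scores (0, 1, …), a single
  "lowest to highest level" slope. Results tables in this literature report
  one coefficient per ordered variable with exactly that contrast, which an
  integer score reproduces; indicator coding is available via
  `scan_config(ordered_as_score = FALSE)` for comparison;
* **unordered categorical** — indicator contrasts against the modal
  category (a deterministic reference choice), with the per-variable p
  taken from the joint F-test on the exposure block so that every variable
  contributes exactly one p-value to the multiplicity correction,
  regardless of its number of levels.

Each model is complete-case in the exposure and outcome; only covariates
are imputed (see below). The per-variable `n` is reported.

## Two-stage multiplicity control

The cohort is partitioned a priori — before any model fitting — into a
discovery set (75%) and a test set (25%) by a seeded simple random split;
`round(n * split_fraction)` subjects go to discovery. Stage 1 fits all
exposures in the discovery set and applies Benjamini–Hochberg (BH) step-up
FDR across them. Stage 2 refits only the discovery-significant variables
in the test set and applies BH across that carried-forward subset only —
our reading of the design; correcting over all variables in stage 2 would
only be more conservative. Bonferroni-adjusted values are reported
alongside at both stages. BH was fixed as the FDR procedure;
Benjamini–Yekutieli is available behind `scan_config(correction =
"fdr_by")`.

Under the complete null with independent tests, BH's FDR equals the
family-wise error rate, so a single stage flags *anything* with
probability $\alpha$ and the two-stage cascade with $\alpha^2$ — for
$\alpha = 0.05$, a 5% and a 0.25% chance of even one false positive across
920 tests. `estimate_fwer()` verifies both rates by simulation, and the
acceptance script recomputes them from scratch.

## Quadratic screening

Continuous exposures are screened in the discovery set for curvature by
adding a centered squared term; if its t-test p falls below $\alpha$ the
term is kept in that variable's model in both stages. Deciding the screen
in the discovery set only avoids test-set leakage. For multi-term models
the per-variable p is the joint F over the whole exposure block.

# Harmonization rules

Raw questionnaire variables are recoded deterministically, in fixed order,
with every step recorded in a replayable audit:

1. **Conditional-question merging.** Skip-logic children are merged into
   their parents: non-gate parent answers keep their label, gate-opened
   subjects take the child's answer (renamed `gate:level` on collisions).
   Chains are merged deepest-first; cyclic parent declarations are a
   dictionary error. Merging happens *before* "do not know" recoding so a
   no-information gate answer propagates to missing.
2. **Type classification.** Declared types are taken as-is; undeclared
   variables are inferred (numeric with > 10 distinct values → continuous;
   declared ordered levels → ordered; otherwise unordered) and the
   inference is flagged in the audit.
3. **"Do not know" recoding.** Declared no-information labels become
   missing and leave the category set.
4. **Category collapsing.** Three rules, in order: (a) ordered variables
   with ≥ 4 levels whose terminal category holds at least
   `lopsided_threshold` of answers collapse to terminal / adjacent /
   pooled remainder; (b) ordered variables with ≥ 5 levels whose middle
   category is modal with at least `centered_threshold` collapse to
   pooled-left / middle / pooled-right; (c) categories under
   `sparse_threshold` merge into their nearest neighbor (ordered) or a
   pooled "other" (unordered) until none remain or two levels are left.

The source descriptions of "leaned to one side" and "centered" are
qualitative; the defaults `lopsided_threshold = 0.5`,
`centered_threshold = 0.4`, `sparse_threshold = 0.05` are this package's
quantification, chosen to reproduce the canonical three-level label
patterns ("Never / Between never and frequent / Frequent") while remaining
configurable and auditable. For even level counts rule (b) takes position
`k %/% 2 + 1` as the middle — an arbitrary but deterministic choice.

# Quality-control cascade

Three dataset-level filters run in fixed order with strict inequalities
("more than", "over"), so boundary cases are retained:

1. drop variables whose modal answer covers **> 95%** of respondents;
2. drop subjects missing **> 60%** of the remaining exposures;
3. drop exposures still missing for **> 50%** of retained subjects.

The modal share is computed among *nonmissing* respondents: whether the
original denominator included missing answers is not documented, and the
nonmissing denominator keeps missingness handling confined to the two
missingness filters. All three thresholds are exposed as arguments so the
robustness sweep (varying them and comparing survivors) can be rerun.

# Outcome scoring

A subject's SRS is excluded when strictly more than 25% of the 18 items
are missing. Otherwise the mean item score is the mean of nonmissing
items; the "weighted total" reported in cohort descriptions is 18 × that
mean, which is the natural reading of a total weighted by the number of
nonmissing items, and the regression outcome is the square root of the
mean item score.

# Covariate sets and imputation

Four nested covariate sets are named: `base` (child age at SRS
assessment), `main6` (+ maternal age, maternal education, maternal
ethnicity, child sex, parity, birth year), `extended8` (+ birth weight,
gestational age — optional because both may be mediators rather than
confounders), and `main6_gsi` (+ the maternal Global Severity Index from
the Brief Symptom Inventory).

Missing covariate values are completed by single-imputation chained
equations: initial mean/mode fill, then sweeps in descending order of
missingness for `n_iter = 10` iterations, each covariate regressed on all
others plus (by default) the outcome — standard practice so that the
imputation model is at least as rich as the analysis model. Continuous
covariates draw prediction-plus-residual-noise; categoricals are modeled
on integer scores and snapped to the nearest observed label, which keeps
draws inside the observed label set. One completed dataset is produced
(the analysis tables are single-result); multiple imputation with pooling
is out of scope. Runs are deterministic given the seed, observed values
are never altered, and a convergence trace (mean absolute change of
imputed values per sweep) is returned. Exposures are never imputed: each
exposure model is complete-case in its own variable.

# Sensitivity analyses

* `exclude_asd` drops subjects with a clinician-confirmed diagnosis flag
  and reruns the full two-stage scan (with zero flagged subjects it is a
  no-op, which is tested).
* `dutch_only` restricts to children of two ethnically Dutch parents.
  Because the subset is much smaller, the split is dropped and only the
  main analysis's surviving variables are re-assessed in one combined set.
* `gsi_adjusted` adds the GSI psychopathology score to the covariates and
  removes the parental-health and parental-psychopathology domains from
  the tested set (their items overlap the adjustment variable).

# The synthetic cohort generator

`synthetic_spec()` defaults describe the study population the package was
built around: 3891 subjects; 920 exposures in ten topical domains
(parental health 260, parental psychopathology 134, sociodemographic 80,
lifestyle and life events 70, nutrition and toxins 120, family and rearing
123, maternal expectations 20, maternal serum biomarkers 60, perinatal and
obstetric 33, cord blood biomarkers 20 — domain totals at the scale such
exposure batteries report, summing to 920); a 40/45/15 mix of
continuous/ordered/unordered types; conditional question pairs and "do not
know" options so every harmonization path is exercised.

**Correlation structure.** One latent standard-normal factor per domain
with loading 0.6 on each of its variables yields within-domain pairwise
correlations of $0.6^2 = 0.36$ and zero between domains — the simplest
generator reproducing the strong block covariance seen in such
questionnaire batteries. No quantitative correlation magnitudes are
available to calibrate against, so the loading is a free, configurable
parameter.

**Missingness.** Exposures are spread over 4 questionnaire waves; each
subject misses a whole wave with probability 0.10 (structural
missingness), plus 5% cell-level MCAR, 2% MCAR on SRS items, and 5% MCAR
on imputable covariates.

**Outcome.** The mean item score is built on the square-root scale:
$\eta_i = \max(\mu + \text{covariate effects} + s\,e_i,\, 0) +
\text{planted effects}$, $\bar S_i = \eta_i^2$ (capped at 3), with $e_i$ a
standardized right-skewed gamma draw (shape 0.5) so the raw-score
distribution is right-skewed and zero-inflated like real SRS data.
Three numerical choices matter for making parameter-recovery experiments
well-posed, and each was verified by direct simulation:

1. *Floor placement.* A nonnegative outcome with mean 0.22 and SD 0.23
   forces 1–2% of latent scores against the zero floor. If planted terms
   enter before the floor, that censoring attenuates every planted slope
   by roughly the floored share (≈ 1–3% of B — small, but an order of
   magnitude above the Monte-Carlo error of a 500-replicate experiment).
   The generator therefore floors the *baseline* (intercept + covariates +
   noise) and adds planted contributions afterwards, shifted to be
   nonnegative wherever the exposure coding is bounded (ordered scores,
   indicators; the shift is a constant absorbed by the calibrated
   intercept). Planted effects on bounded codings then never meet the
   floor and are recovered exactly; continuous (Gaussian) codings are
   unbounded below, so a final floor still touches their far left tail —
   an irreducible consequence of a nonnegative outcome, documented rather
   than hidden. Recovery experiments also plant one effect at a time:
   several simultaneous effects of realistic magnitude push the bounded
   outcome outside its feasible moment range.
2. *Calibration.* The intercept $\mu$ and noise scale $s$ are solved by
   nested root-finding so the realized mean item score hits the target
   mean 0.22 / SD 0.23. Closed-form normal moment matching misses the SD
   badly (the skewed noise's fourth moment dominates the variance of
   $\eta^2$), and solving on the outcome's own noise draws couples the
   noise to the exposures and measurably biases slopes — so the solve
   uses an independent reference noise draw. Neither parameter touches
   the planted or covariate coefficients.
3. *Item quantization.* Eighteen integer items can only encode mean
   scores on a 1/18 grid. Deterministic rounding of the item total
   inflates fitted slopes by 1–2% of B through sqrt-scale scalloping;
   the generator instead randomizes the total between the two bracketing
   grid points with the probability that makes $\sqrt{T/18}$
   conditionally unbiased for $\eta$ — quantization then adds noise but
   no systematic distortion on the scale the model fits.

Covariate effects default to literature-scale magnitudes (e.g., −0.007 per
maternal year, +0.063 for boys, +0.158 for low maternal education, +0.097
for nonwestern maternal ethnicity, −1.2e−5 per gram of birth weight, all
on the square-root scale).

**Planted structure for sensitivity tests.** `plant_mediation()` reroutes
a chosen share of a planted effect through the GSI mediator while keeping
the total effect fixed, so GSI adjustment should recover only the direct
part; `confounded_ethnicity` shifts chosen exposures by nonwestern
ethnicity without any direct outcome effect, so their marginal association
must vanish in the Dutch-only subset. Note that exposures in the
parental-psychopathology domain are confounded with the GSI path *by
construction* (both load on the same latent factor), which is intended —
it reproduces the adjustment-sensitivity of that domain — but means
unbiasedness checks must plant effects in other domains.

**What the generator does not emulate:** real questionnaire text or item
semantics, informative (non-MCAR beyond wave structure) missingness,
cross-domain correlation, measurement error in biomarkers, or rater
effects. Passing tests therefore demonstrate correctness of the machinery
under the stated generative assumptions, not robustness to every
real-data pathology.

# Error-rate simulation

`estimate_fwer()` uses a vectorized kernel: per replicate, an $n \times m$
matrix of independent standard-normal exposures, an independent outcome,
closed-form simple-regression p-values, BH at $\alpha$, and (for the
two-stage design) the split-carry-refit cascade. The closed form equals
the `lm`-based kernel to 1e-10 on identical data (regression-tested).
FWER replicates default to $n = 500$ subjects because the null rejection
probability does not depend on $n$ beyond t-distribution degrees of
freedom. Reported estimates carry exact binomial 95% CIs.

# Numerical and degenerate-case choices

* Exposures constant after complete-case restriction, or collinear with
  the covariates, are skipped and logged per stage (classed conditions
  `enwas_degenerate_fit` / `enwas_rank_deficient`); covariates enter the
  model matrix first so collinearity aliases the exposure term, which is
  the detectable condition.
* Covariate columns that are constant in a subset (ethnicity in the
  Dutch-only analysis) are dropped from the model matrix.
* Significance is `adjusted p <= alpha`, matching the BH step-up rejection
  rule exactly; with continuous p-values the boundary has probability
  zero.
* Manhattan plots default to the −log10 *FDR-adjusted* p axis, on which
  the red line at −log10(0.05) separates FDR-significant variables
  exactly; the green (uncorrected) and purple (Bonferroni) lines are
  mapped onto that axis through the realized raw-to-adjusted step
  function, a documented convention since no exact placement rule for
  mixed thresholds on an adjusted axis exists. A raw-p axis with textbook
  line positions is available via `adjusted = FALSE`.

# Problem sizes used by the test suite

Unit and property tests run on cohorts of 150–2,500 subjects with a
34-variable, ten-domain layout; distribution checks use up to 6,000
subjects. The error-rate checks run the study-scale design: 1,000 null
replicates of 920 exposures for the single-stage rate and 4,000 replicates
for the two-stage rate; parameter recovery uses 500 replicates of 700
subjects per planted effect (0.05, 0.10 and 0.15 on the square-root
scale, one ordered-coded effect per experiment). These sizes were chosen so the whole suite runs on a single CPU in
well under half an hour while keeping Monte-Carlo error small relative to
the tolerances tested.

# Known limitations

* Ordered-categorical effects assume linearity in level scores; the
  indicator-coding option exists precisely to check that assumption.
* The two-stage FWER guarantee ($\alpha^2$) is derived under independent
  tests and the complete null; with the strong within-domain correlation
  of real exposure batteries the realized rate can differ — that caveat
  belongs to the design itself, not to this implementation, and the
  simulation module only certifies the independent-null arithmetic.
* Single imputation understates covariate-imputation uncertainty; with
  covariate missingness around 5% the effect on scan inference is small,
  but formally the CIs do not propagate it.
* The split mechanism is unstratified simple random sampling; exact
  subject counts of any particular historical analysis are not
  reproduced.
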