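# enwasr

Environment-wide association scans (EnWAS) for epidemiological cohorts:
screen hundreds of mixed-type prenatal/perinatal exposures against a
continuous childhood trait with a reproducible, fully audited pipeline.

An EnWAS is the exposome analogue of a GWAS: one covariate-adjusted linear
model per exposure, a single p-value per variable, and strict
multiple-testing control. `enwasr` implements the whole workflow for an
18-item Social Responsiveness Scale (SRS) outcome:

* **Harmonization** — dictionary-driven recoding of raw questionnaire
  variables: conditional (skip-logic) questions merged into their parents,
  "do not know" answers blanked, sparse or lopsided category sets
  collapsed by fixed rules; every step lands in a replayable audit log.
* **Quality control** — the exclusion cascade: variables with > 95% modal
  answers, subjects with > 60% missing exposures, variables with > 50%
  missingness (strict inequalities; boundaries retained).
* **Outcome scoring** — mean SRS item score with the > 25% missing-item
  exclusion rule, 18 × mean weighted total, and the square-root transform
  used as the regression outcome `y`.
* **Covariate imputation** — single-imputation chained equations so every
  per-exposure model sees a complete covariate matrix; exposures are never
  imputed (complete-case per variable).
* **The scan** — a priori 75/25 discovery/test split; per-variable OLS of

  `sqrt(mean SRS item score) ~ exposure + covariates`

  with continuous slopes, integer-score slopes for ordered categoricals
  ("lowest to highest level"), and joint-F indicator contrasts for
  unordered ones; Benjamini–Hochberg FDR in the discovery set, then again
  across the carried-forward variables in the held-out test set, with
  Bonferroni reported alongside; optional quadratic screening of
  continuous exposures; Dutch-only, ASD-exclusion and
  psychopathology-adjusted (GSI) sensitivity modes.
* **Synthetic cohorts** — a generator emulating the study structure (920
  exposures in 10 correlated domains, wave-structured missingness,
  calibrated right-skewed outcome, literature-scale covariate effects,
  plantable exposure/mediation/confounding effects) so the machinery is
  testable without restricted data.
* **Design validation** — simulation of the family-wise false-positive
  rate of the one- and two-stage designs, and of power for planted
  effects.
* **Reporting** — Manhattan plots with uncorrected/FDR/Bonferroni
  threshold lines, domain-ordered correlation heatmaps, nonresponse
  comparisons, and significance-count tables.

## Worked example

```r
library(enwasr)

# a synthetic cohort: 2,000 subjects, 34 variables in 10 domains,
# one planted continuous effect of 0.10 on the square-root outcome scale
domains <- c(parental_health = 4, parental_psychopathology = 4,
             sociodemographic = 3, lifestyle_life_events = 3,
             nutrition_toxins = 3, family_rearing = 3,
             maternal_expectations = 2, maternal_biomarkers = 3,
             perinatal_obstetric = 2, cord_blood_biomarkers = 2)
spec <- synthetic_spec(n_subjects = 2000, domains = domains,
                       planted_effects = c(prntl_h_v002 = 0.10), seed = 42)
coh <- generate_cohort(spec)

# harmonize -> QC -> outcome -> impute -> scan
h   <- harmonize_cohort(coh$data, coh$dictionary)
qc  <- qc_filter(h$data, names(h$dictionary))
d   <- add_srs_outcome(qc$data)
d   <- d[!d$srs_excluded & !is.na(d$y), ]
imp <- impute_covariates(d, c("maternal_age", "maternal_education",
                              "parity", "gestational_age", "birth_weight",
                              "gsi"), outcome = "y", seed = 7)
scan <- run_enwas(imp$data, h$dictionary,
                  scan_config(covariate_set = "main6", seed = 11))
print(scan)
#> <enwas_scan>
#>           total p05 fdr bonferroni
#> discovery    24   7   5          5
#> test          5   4   4          4
#> surviving variables: 4
```

The discovery stage tested 24 harmonized variables (conditional pairs
merge away some of the 29, and the QC cascade removes near-constant
ones); 5 passed FDR and were carried to the test set, where 4 survived a
second FDR pass — the planted variable among them:

```r
subset(scan$results, stage == "test" & variable == "prntl_h_v002",
       c(variable, n, B, CI_low, CI_high, p_joint, p_fdr))
#>       variable   n      B CI_low CI_high  p_joint    p_fdr
#> 37 prntl_h_v002 431 0.0911 0.0754   0.107 1.85e-26 9.26e-26
```

`B` is the effect per SD of exposure on the square-root outcome scale;
the planted 0.10 is close to the estimate (its CI reflects the test-set
subjects only). The extra survivors are the planted variable's correlated
domain-mates and psychopathology items that share a latent factor with
the GSI covariate path — the "high covariance" behavior these scans show
on real data.

```r
manhattan_plot(scan$results, out_file = "manhattan.png")
counts_table(list(main6 = scan$report))
```

Design-level error rates (the 5% / 0.25% arithmetic for 920 independent
null tests) are recomputed by:

```r
estimate_fwer(m = 920, n = 500, stages = 1, n_reps = 1000, seed = 1)
estimate_fwer(m = 920, n = 800, stages = 2, n_reps = 4000, seed = 2)
```

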