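test_that("default dictionary reproduces the study layout: 920 variables, 10 domains", {
  dict <- generate_dictionary(synthetic_spec())
  expect_length(dict, 920L)
  doms <- vapply(dict, function(r) r$domain, character(1))
  expect_length(unique(doms), 10L)
  expect_equal(sum(doms == "parental_health"), 260L)
  expect_equal(sum(doms == "parental_psychopathology"), 134L)
  # conditional pairs and dk options present to exercise harmonization
  parents <- vapply(dict, function(r) !is.null(r$parent), logical(1))
  expect_equal(sum(parents), 5L)
  dk <- vapply(dict, function(r) length(r$dont_know_labels) > 0, logical(1))
  expect_gt(sum(dk), 0L)
  # no conditional pairs requested -> none emitted
  d0 <- generate_dictionary(small_spec(n = 10, n_conditional = 0))
  expect_false(any(vapply(d0, function(r) !is.null(r$parent), logical(1))))
})

test_that("cohort generation is reproducible and has the contracted shape", {
  spec <- small_spec(n = 300, seed = 17)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$data, c2$data)
  expect_equal(nrow(c1$data), 300L)
  expect_true(all(names(c1$dictionary) %in% names(c1$data)))
  expect_length(grep("^srs_item_", names(c1$data)), 18L)
  expect_true(all(c("age_srs", "maternal_age", "maternal_education",
                    "maternal_ethnicity", "child_sex", "parity", "birth_year",
                    "birth_weight", "gestational_age", "gsi", "asd_dx",
                    "dutch_parents") %in% names(c1$data)))
})

test_that("latent-factor blocks give within-domain correlation near loading^2", {
  spec <- small_spec(n = 2500, seed = 23, wave_missing_rate = 0,
                     item_missing_rate = 0, dk_rate = 0, n_conditional = 0)
  coh <- generate_cohort(spec)
  cont <- names(coh$dictionary)[vapply(coh$dictionary, function(r)
    r$var_type == "continuous", logical(1))]
  doms <- vapply(coh$dictionary[cont], function(r) r$domain, character(1))
  cm <- cor(as.matrix(coh$data[, cont]))
  same <- outer(doms, doms, "==") & upper.tri(cm)
  diff <- !outer(doms, doms, "==") & upper.tri(cm)
  expect_equal(mean(cm[same]), 0.36, tolerance = 0.05)
  expect_lt(mean(abs(cm[diff])), 0.05)
})

test_that("outcome marginals match the configured mean/SD of the mean item score", {
  spec <- small_spec(n = 4000, seed = 29, srs_item_missing_rate = 0)
  coh <- generate_cohort(spec)
  sc <- score_srs(coh$data[, grep("^srs_item_", names(coh$data))])
  expect_equal(mean(sc$mean_item_score), 0.22, tolerance = 0.025)
  expect_equal(sd(sc$mean_item_score), 0.23, tolerance = 0.05)
  expect_true(all(sc$mean_item_score >= 0 & sc$mean_item_score <= 3))
})

test_that("realized missingness rates track the spec", {
  spec <- small_spec(n = 2000, seed = 41, wave_missing_rate = 0.10,
                     item_missing_rate = 0.05, dk_rate = 0, n_conditional = 0)
  coh <- generate_cohort(spec)
  miss <- mean(is.na(as.matrix(coh$data[, names(coh$dictionary)])))
  # wave + item MCAR compose to ~ 1 - 0.9 * 0.95
  expect_equal(miss, 1 - 0.90 * 0.95, tolerance = 0.02)
})

test_that("a planted effect is recovered by a covariate-adjusted fit", {
  dict <- generate_dictionary(small_spec(n = 10, seed = 3, n_conditional = 0))
  v <- continuous_by_domain(dict)[3]
  spec <- small_spec(n = 4000, seed = 3, n_conditional = 0,
                     wave_missing_rate = 0, item_missing_rate = 0,
                     srs_item_missing_rate = 0, covariate_missing_rate = 0,
                     planted_effects = stats::setNames(0.10, v))
  coh <- generate_cohort(spec)
  d <- add_srs_outcome(coh$data)
  covs <- covariate_sets()$main6
  f <- fit_exposure_model(d$y, d[[v]], d[, covs], var_type = "continuous",
                          name = v)
  expect_lt(abs(f$contrasts$B - 0.10), 0.015)    # ~3.5 standard errors
  expect_lt(f$contrasts$p_joint, 1e-8)
})

test_that("null cohorts yield uniform exposure p-values", {
  spec <- small_spec(n = 700, seed = 53, loading = 0, gsi_effect = 0,
                     n_conditional = 0, wave_missing_rate = 0,
                     item_missing_rate = 0, dk_rate = 0,
                     srs_item_missing_rate = 0, covariate_missing_rate = 0)
  coh <- generate_cohort(spec)
  d <- add_srs_outcome(coh$data)
  cont <- names(coh$dictionary)[vapply(coh$dictionary, function(r)
    r$var_type == "continuous", logical(1))]
  # covariates do affect y; adjust for them so exposures are pure null
  covs <- covariate_sets()$main6
  p <- vapply(cont, function(v)
    fit_exposure_model(d$y, d[[v]], d[, covs], var_type = "continuous",
                       name = v)$contrasts$p_joint, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("mediation rewiring preserves the total effect and removes it under adjustment", {
  dict <- generate_dictionary(small_spec(n = 10, seed = 7, n_conditional = 0))
  v <- continuous_by_domain(dict)[4]
  base <- small_spec(n = 6000, seed = 7, n_conditional = 0,
                     wave_missing_rate = 0, item_missing_rate = 0,
                     srs_item_missing_rate = 0, covariate_missing_rate = 0,
                     gsi_effect = 0.10,
                     planted_effects = stats::setNames(0.12, v))
  expect_identical(plant_mediation(base, v, 0), base)
  expect_error(plant_mediation(base, v, 1.2), class = "enwas_spec_error")
  expect_error(plant_mediation(base, "ghost", 0.5), class = "enwas_spec_error")
  half <- plant_mediation(base, v, 0.5)
  coh <- generate_cohort(half)
  d <- add_srs_outcome(coh$data)
  unadj <- fit_exposure_model(d$y, d[[v]], NULL, "continuous", name = v)
  adj <- fit_exposure_model(d$y, d[[v]],
                            d[, c("age_srs", "gsi")], "continuous", name = v)
  expect_lt(abs(unadj$contrasts$B - 0.12), 0.015)   # total preserved
  expect_lt(abs(adj$contrasts$B - 0.06), 0.015)     # direct = half
})

test_that("synthetic artifacts round-trip through disk", {
  coh <- generate_cohort(small_spec(n = 60, seed = 19))
  dir <- withr::local_tempdir()
  write_synthetic(coh, dir)
  expect_true(all(file.exists(file.path(dir, c("data.tsv", "dictionary.yaml",
                                               "truth.json")))))
  d2 <- read_cohort(file.path(dir, "data.tsv"))
  expect_equal(dim(d2), dim(coh$data))
  dict2 <- read_dictionary(file.path(dir, "dictionary.yaml"))
  expect_equal(names(dict2), names(coh$dictionary))
})
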