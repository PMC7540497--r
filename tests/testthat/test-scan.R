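test_that("discovery/test split is an exhaustive, seeded, a-priori partition", {
  d <- data.frame(subject_id = 1:100, x = rnorm(100))
  sp <- split_cohort(d, 0.75, seed = 5)
  expect_equal(nrow(sp$discovery), 75L)
  expect_equal(nrow(sp$test), 25L)
  expect_setequal(c(sp$discovery$subject_id, sp$test$subject_id), 1:100)
  expect_length(intersect(sp$discovery$subject_id, sp$test$subject_id), 0L)
  sp2 <- split_cohort(d, 0.75, seed = 5)
  expect_identical(sp, sp2)
  # rounding rule
  d2 <- data.frame(subject_id = 1:3841)
  expect_equal(nrow(split_cohort(d2, 0.75, 1)$discovery), 2881L)
  expect_error(split_cohort(d[1, , drop = FALSE], 0.75, 1),
               class = "enwas_config_error")
})

test_that("exposure models reproduce exact least-squares solutions", {
  # noiseless line ("perfect fit" warnings from lm are expected here)
  f <- suppressWarnings(fit_exposure_model(c(1, 3, 5, 7), c(0, 1, 2, 3)))
  expect_equal(f$contrasts$B, 2, tolerance = 1e-10)
  expect_equal(f$contrasts$B_intercept, 1, tolerance = 1e-10)
  # worked 5-row table, normal equations by hand: Sxy=8, Sxx=10
  f2 <- fit_exposure_model(c(2, 1, 4, 3, 5), c(1, 2, 3, 4, 5))
  expect_equal(f2$contrasts$B, 0.8, tolerance = 1e-10)
  expect_equal(f2$contrasts$B_intercept, 0.6, tolerance = 1e-10)
  expect_true(f2$contrasts$CI_low <= f2$contrasts$B &&
                f2$contrasts$B <= f2$contrasts$CI_high)
})

test_that("null slopes are within 3 standard errors almost always", {
  set.seed(61)
  inside <- replicate(200, {
    x <- rnorm(500)
    y <- rnorm(500)
    f <- fit_exposure_model(y, x)$contrasts
    se <- (f$CI_high - f$B) / qt(0.975, f$n - 2)
    abs(f$B) < 3 * se
  })
  expect_gte(mean(inside), 0.98)
})

test_that("exposure codings: ordered scores, unordered contrasts with joint F", {
  set.seed(62)
  n <- 400
  score <- sample(0:3, n, TRUE)
  y <- 0.5 + 0.2 * score + rnorm(n, 0, 0.4)
  lev <- c("never", "rarely", "often", "always")
  f <- fit_exposure_model(y, lev[score + 1], var_type = "ordered_categorical",
                          category_order = lev)
  expect_equal(nrow(f$contrasts), 1L)            # one lowest-to-highest slope
  expect_lt(abs(f$contrasts$B - 0.2), 0.06)      # ~3 standard errors

  g <- sample(c("a", "b", "c"), n, TRUE)
  y2 <- 0.3 + 0.4 * (g == "c") + rnorm(n, 0, 0.4)
  f2 <- fit_exposure_model(y2, g, var_type = "unordered_categorical",
                           category_order = c("a", "b", "c"))
  expect_equal(nrow(f2$contrasts), 2L)           # k-1 contrasts vs modal ref
  expect_length(unique(f2$contrasts$p_joint), 1L)
  # joint F must match an independent drop-one anova on the same data
  df <- data.frame(y2, g)
  oracle <- anova(lm(y2 ~ 1, df), lm(y2 ~ g, df))[2, "Pr(>F)"]
  expect_equal(f2$contrasts$p_joint[1], oracle, tolerance = 1e-12)
})

test_that("degenerate exposures raise classed errors", {
  expect_error(fit_exposure_model(rnorm(10), rep(1, 10)),
               class = "enwas_degenerate_fit")
  x <- rnorm(20)
  expect_error(fit_exposure_model(rnorm(20), x,
                                  covariates = data.frame(c1 = 2 * x)),
               class = "enwas_rank_deficient")
})

test_that("quadratic screening flags curvature and skips categoricals", {
  set.seed(63)
  x <- rnorm(600)
  y <- 0.3 * (x - mean(x))^2 + rnorm(600, 0, 0.2)
  sq <- screen_quadratic(y, x)
  expect_true(sq$retain)
  expect_lt(sq$p_quadratic, 1e-10)
  expect_null(screen_quadratic(y, sample(c("a", "b"), 600, TRUE),
                               var_type = "unordered_categorical"))
  # under a linear truth the quadratic term is retained ~alpha of the time
  retained <- replicate(300, {
    x <- rnorm(200)
    screen_quadratic(0.5 * x + rnorm(200), x)$retain
  })
  expect_equal(mean(retained), 0.05, tolerance = 0.035)
})

test_that("p-value adjustment matches hand-derived cases", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr_bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03, "fdr_bh"), 0.03)
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(rep(1e-4, 920), "bonferroni"),
               rep(0.092, 920))
  expect_length(adjust_pvalues(numeric(0)), 0L)
  expect_error(adjust_pvalues(c(0.5, 0)), class = "enwas_config_error")
  # small brute-force cross-check (the full 1000-vector sweep is in the
  # acceptance suite)
  set.seed(64)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    expect_equal(adjust_pvalues(p, "fdr_bh"), bh_oracle(p))
  }
})

test_that("two-stage scan contracts: carry-forward, counts, determinism", {
  dict <- generate_dictionary(small_spec(n = 10, seed = 37))
  v <- continuous_by_domain(dict)[5]
  coh <- generate_cohort(small_spec(n = 1500, seed = 37,
                                    planted_effects = stats::setNames(0.15, v)))
  prep <- prepare_cohort(coh)
  cfg <- scan_config(seed = 2)
  s1 <- run_enwas(prep$data, prep$dictionary, cfg)
  s2 <- run_enwas(prep$data, prep$dictionary, cfg)
  expect_identical(s1$results, s2$results)                 # determinism
  st <- s1$report$stages
  expect_equal(st["test", "total"], st["discovery", "fdr"]) # carry-forward
  expect_true(v %in% s1$report$surviving)                   # planted survives
  one <- s1$results[!duplicated(paste(s1$results$variable, s1$results$stage)), ]
  expect_true(all(one$p_fdr >= one$p_joint - 1e-15))
  expect_true(all(one$p_bonf >= one$p_joint - 1e-15))
  ndisc <- round(nrow(prep$data) * 0.75)
  expect_true(all(one$n[one$stage == "discovery"] <= ndisc))
  expect_true(all(one$n[one$stage == "test"] <= nrow(prep$data) - ndisc))
})

test_that("sensitivity modes implement their contracts", {
  dict <- generate_dictionary(small_spec(n = 10, seed = 43))
  v <- continuous_by_domain(dict)[6]
  coh <- generate_cohort(small_spec(n = 1500, seed = 43, asd_flag_rate = 0,
                                    planted_effects = stats::setNames(0.15, v)))
  prep <- prepare_cohort(coh)
  cfg <- scan_config(seed = 2, quadratic_screen = FALSE)
  main <- run_enwas(prep$data, prep$dictionary, cfg)
  # excluding zero ASD cases is a no-op
  noasd <- run_sensitivity(prep$data, prep$dictionary, cfg, "exclude_asd")
  expect_identical(main$results, noasd$results)
  # gsi adjustment drops the parental-health/psychopathology domains
  gsi <- run_sensitivity(prep$data, prep$dictionary, cfg, "gsi_adjusted")
  doms <- unique(gsi$results$domain)
  expect_false(any(c("parental_health", "parental_psychopathology") %in% doms))
  # dutch-only: single combined stage over the supplied hits
  du <- run_sensitivity(prep$data, prep$dictionary, cfg, "dutch_only",
                        main_hits = main$report$surviving)
  expect_equal(unique(du$results$stage), "combined")
  expect_setequal(unique(du$results$variable), main$report$surviving)
  # config errors for missing indicator columns
  d2 <- prep$data[, setdiff(names(prep$data), "dutch_parents")]
  expect_error(run_sensitivity(d2, prep$dictionary, cfg, "dutch_only"),
               class = "enwas_config_error")
})

test_that("results table serializes with the documented columns", {
  coh <- generate_cohort(small_spec(n = 400, seed = 47))
  prep <- prepare_cohort(coh)
  scan <- run_enwas(prep$data, prep$dictionary,
                    scan_config(seed = 1, quadratic_screen = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(scan, path)
  tab <- read.delim(path)
  expect_true(all(c("variable", "domain", "var_type", "contrast", "n", "B",
                    "B_intercept", "CI_low", "CI_high", "p_joint",
                    "p_quadratic", "stage", "p_fdr", "p_bonf", "sig_fdr",
                    "sig_bonf") %in% names(tab)))
})
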