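# Mass-univariate environment-wide scan. One covariate-adjusted linear
# model per exposure on the square-root SRS outcome; joint p per variable;
# Benjamini-Hochberg FDR across the discovery set, then again across the
# carried-forward variables in the held-out test set. Bonferroni reported
# alongside. Ordered categoricals enter as consecutive-integer scores
# (one "lowest to highest level" effect), unordered categoricals as
# indicator contrasts against the modal reference level with a joint F-test.

#' Named covariate sets
#'
#' `base` adjusts only for child age at SRS assessment; `main6` adds the six
#' most common epidemiological covariates (maternal age, education and
#' ethnicity, child sex, parity, birth year); `extended8` adds birth weight
#' and gestational age; `main6_gsi` adds the maternal GSI psychopathology
#' score to `main6`. The sets are nested: base < main6 < extended8.
#'
#' @return Named list of covariate column-name vectors.
#' @export
covariate_sets <- function() {
  base <- "age_srs"
  main6 <- c(base, "maternal_age", "maternal_education", "maternal_ethnicity",
             "child_sex", "parity", "birth_year")
  list(base = base,
       main6 = main6,
       extended8 = c(main6, "birth_weight", "gestational_age"),
       main6_gsi = c(main6, "gsi"))
}

#' Configure an environment-wide scan
#'
#' @param split_fraction Discovery share of the cohort (default 0.75).
#' @param seed Seed for the discovery/test split.
#' @param covariate_set One of `names(covariate_sets())`.
#' @param alpha Significance level (default 0.05).
#' @param correction `"fdr_bh"` (Benjamini-Hochberg, default), `"fdr_by"`,
#'   or `"bonferroni"` as the gatekeeping correction between stages.
#' @param quadratic_screen Screen continuous exposures for a quadratic term
#'   in the discovery stage and keep it in both stages when significant.
#' @param sensitivity One of `"none"`, `"dutch_only"`, `"exclude_asd"`,
#'   `"gsi_adjusted"`.
#' @param outcome_col Outcome column (default `"y"`, the square-root mean
#'   SRS item score).
#' @param ordered_as_score Model ordered categoricals as integer scores
#'   (default) rather than indicator contrasts.
#' @return A `scan_config` list.
#' @export
scan_config <- function(split_fraction = 0.75, seed = 1L,
                        covariate_set = "main6", alpha = 0.05,
                        correction = "fdr_bh", quadratic_screen = TRUE,
                        sensitivity = "none", outcome_col = "y",
                        ordered_as_score = TRUE) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_enwas("split_fraction must be in (0, 1)", "enwas_config_error")
  }
  if (!covariate_set %in% names(covariate_sets())) {
    stop_enwas(sprintf("unknown covariate_set '%s'", covariate_set),
               "enwas_config_error")
  }
  if (!correction %in% c("fdr_bh", "fdr_by", "bonferroni")) {
    stop_enwas(sprintf("unknown correction '%s'", correction), "enwas_config_error")
  }
  if (!sensitivity %in% c("none", "dutch_only", "exclude_asd", "gsi_adjusted")) {
    stop_enwas(sprintf("unknown sensitivity mode '%s'", sensitivity),
               "enwas_config_error")
  }
  structure(list(split_fraction = split_fraction, seed = as.integer(seed),
                 covariate_set = covariate_set, alpha = alpha,
                 correction = correction, quadratic_screen = quadratic_screen,
                 sensitivity = sensitivity, outcome_col = outcome_col,
                 ordered_as_score = ordered_as_score),
            class = "scan_config")
}

#' Split a cohort into discovery and test sets
#'
#' A priori simple random partition, performed before any model fitting;
#' discovery size is `round(n * split_fraction)`. Deterministic for a fixed
#' seed.
#'
#' @param data Cohort data frame.
#' @param split_fraction Discovery share.
#' @param seed RNG seed.
#' @return List with `discovery` and `test` data frames (disjoint,
#'   exhaustive, original row order preserved within each part).
#' @export
split_cohort <- function(data, split_fraction = 0.75, seed = 1L) {
  n <- nrow(data)
  if (n < 2L) stop_enwas("need at least 2 subjects to split", "enwas_config_error")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_enwas("split_fraction must be in (0, 1)", "enwas_config_error")
  }
  idx <- with_seed(seed, sort(sample.int(n, round(n * split_fraction))))
  list(discovery = data[idx, , drop = FALSE],
       test = data[-idx, , drop = FALSE])
}

# numeric exposure coding for model fitting
code_exposure <- function(x, var_type, category_order = NULL) {
  if (var_type == "continuous") return(list(frame = data.frame(.x = as.numeric(x)),
                                            labels = "per unit"))
  lev <- category_order %||% sort(unique(stats::na.omit(x)))
  lev <- lev[lev %in% x]
  if (var_type == "ordered_categorical") {
    list(frame = data.frame(.x = match(x, lev) - 1),
         labels = sprintf("%s to %s (per level)", lev[1L], lev[length(lev)]))
  } else {
    ref <- modal_level(x)
    lev <- c(ref, setdiff(lev, ref))
    list(frame = data.frame(.x = factor(x, levels = lev)),
         labels = sprintf("%s vs %s", setdiff(lev, ref), ref))
  }
}

#' Fit one covariate-adjusted exposure model
#'
#' Ordinary least squares of the outcome on the exposure coding plus
#' covariates, complete-case for this variable. Continuous exposures get one
#' slope (optionally plus a centered quadratic term), ordered categoricals a
#' single lowest-to-highest slope on integer scores, unordered categoricals
#' per-level contrasts against the modal reference with a joint F-test
#' providing the single per-variable p.
#'
#' @param y Outcome vector.
#' @param x Exposure vector.
#' @param covariates Optional data frame of (already imputed) covariates.
#' @param var_type Exposure type label.
#' @param category_order Category order for categoricals.
#' @param quadratic Include a centered quadratic exposure term.
#' @param name,domain Metadata carried into the result.
#' @return An `enwas_fit`: one row per contrast with `B`, 95% CI, plus
#'   `p_joint`, `B_intercept` and the complete-case `n`. Degenerate or
#'   rank-deficient exposures raise conditions of class
#'   `enwas_degenerate_fit` / `enwas_rank_deficient`.
#' @export
fit_exposure_model <- function(y, x, covariates = NULL,
                               var_type = "continuous",
                               category_order = NULL, quadratic = FALSE,
                               name = "x", domain = NA_character_) {
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]
  x <- x[keep]
  if (length(unique(x)) < 2L) {
    stop_enwas(sprintf("exposure '%s' constant after complete-case restriction",
                       name), "enwas_degenerate_fit")
  }
  coding <- code_exposure(x, var_type, category_order)
  df <- coding$frame
  if (quadratic && var_type == "continuous") {
    df$.x <- df$.x - mean(df$.x)
    df$.x2 <- df$.x^2
  }
  # covariates first: under collinearity lm then aliases the exposure term,
  # which is the condition we must detect
  if (!is.null(covariates)) df <- cbind(covariates[keep, , drop = FALSE], df)
  df$.y <- y
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  xterms <- grep("^\\.x", names(cf), value = TRUE)
  if (anyNA(cf[xterms])) {
    stop_enwas(sprintf("exposure '%s' collinear with covariates", name),
               "enwas_rank_deficient")
  }
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(stats::confint(fit))
  main_terms <- setdiff(xterms, ".x2")
  p_joint <- if (length(xterms) == 1L) {
    sm[xterms, "Pr(>|t|)"]
  } else {
    df0 <- df[, setdiff(names(df), c(".x", ".x2")), drop = FALSE]
    fit0 <- if (ncol(df0) == 1L) stats::lm(.y ~ 1, data = df0)
            else stats::lm(.y ~ ., data = df0)
    stats::anova(fit0, fit)[2L, "Pr(>F)"]
  }
  p_quadratic <- if (".x2" %in% xterms) sm[".x2", "Pr(>|t|)"] else NA_real_
  contrasts <- data.frame(
    variable = name, domain = domain, var_type = var_type,
    contrast = coding$labels,
    n = length(y),
    B = unname(cf[main_terms]),
    B_intercept = unname(cf["(Intercept)"]),
    CI_low = unname(ci[main_terms, 1L]),
    CI_high = unname(ci[main_terms, 2L]),
    p_joint = unname(p_joint),
    p_quadratic = unname(p_quadratic),
    stringsAsFactors = FALSE)
  structure(list(contrasts = contrasts, n = length(y),
                 quadratic = quadratic && var_type == "continuous"),
            class = "enwas_fit")
}

#' Screen a continuous exposure for curvature
#'
#' Fits outcome ~ exposure + centered-exposure-squared + covariates and
#' returns the quadratic coefficient's two-sided p. Decided in the discovery
#' stage only, to avoid test-set leakage.
#'
#' @inheritParams fit_exposure_model
#' @param alpha Retention threshold.
#' @return List with `p_quadratic` and `retain` flag; `NULL` (not
#'   applicable) for categorical exposures.
#' @export
screen_quadratic <- function(y, x, covariates = NULL, alpha = 0.05,
                             var_type = "continuous", name = "x") {
  if (var_type != "continuous") return(NULL)
  fit <- fit_exposure_model(y, x, covariates, var_type = "continuous",
                            quadratic = TRUE, name = name)
  p <- fit$contrasts$p_quadratic[1L]
  list(p_quadratic = p, retain = is.finite(p) && p < alpha)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up FDR (default), Benjamini-Yekutieli, or
#' Bonferroni (`min(1, m p)`).
#'
#' @param p Vector of p-values in (0, 1].
#' @param method `"fdr_bh"`, `"fdr_by"`, or `"bonferroni"`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
adjust_pvalues <- function(p, method = c("fdr_bh", "fdr_by", "bonferroni")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop_enwas("p-values must lie in (0, 1]", "enwas_config_error")
  }
  stats::p.adjust(p, switch(method, fdr_bh = "BH", fdr_by = "BY",
                            bonferroni = "bonferroni"))
}

# fit every exposure in `data`, returning the one-row-per-contrast table
fit_stage <- function(data, variables, dictionary, config, stage,
                      quad_retained = character()) {
  covs <- covariate_sets()[[config$covariate_set]]
  if (config$sensitivity == "gsi_adjusted") covs <- union(covs, "gsi")
  missing_covs <- setdiff(covs, names(data))
  if (length(missing_covs)) {
    stop_enwas(sprintf("covariates absent from table: %s",
                       paste(missing_covs, collapse = ", ")),
               "enwas_config_error")
  }
  cov_df <- drop_constant_cols(data[, covs, drop = FALSE])
  y <- data[[config$outcome_col]]
  rows <- list()
  skipped <- list()
  for (v in variables) {
    r <- dictionary[[v]]
    vt <- if (!is.null(r)) r$var_type else
      if (is.numeric(data[[v]])) "continuous" else "unordered_categorical"
    if (!config$ordered_as_score && vt == "ordered_categorical") {
      vt <- "unordered_categorical"
    }
    res <- tryCatch(
      fit_exposure_model(y, data[[v]], cov_df, var_type = vt,
                         category_order = if (!is.null(r)) r$levels,
                         quadratic = v %in% quad_retained,
                         name = v, domain = if (!is.null(r)) r$domain else NA),
      enwas_degenerate_fit = function(e) e,
      enwas_rank_deficient = function(e) e,
      error = function(e) e)
    if (inherits(res, "condition")) {
      skipped[[v]] <- conditionMessage(res)
      next
    }
    rows[[v]] <- res$contrasts
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    rownames(out) <- NULL
    out$stage <- stage
  }
  list(results = out, skipped = skipped)
}

# stage-level multiplicity: adjust the per-variable joint p across the
# variables tested in this stage, replicate onto contrast rows
adjust_stage <- function(results, alpha, correction) {
  pv <- tapply(results$p_joint, results$variable, `[`, 1L)
  adj <- adjust_pvalues(unname(pv), if (correction == "fdr_by") "fdr_by" else "fdr_bh")
  bonf <- adjust_pvalues(unname(pv), "bonferroni")
  i <- match(results$variable, names(pv))
  results$p_fdr <- adj[i]
  results$p_bonf <- bonf[i]
  results$sig_fdr <- results$p_fdr <= alpha
  results$sig_bonf <- results$p_bonf <= alpha
  results
}

stage_counts <- function(results, alpha) {
  if (is.null(results) || nrow(results) == 0L) {
    return(c(total = 0L, p05 = 0L, fdr = 0L, bonferroni = 0L))
  }
  one <- results[!duplicated(results$variable), ]
  c(total = nrow(one), p05 = sum(one$p_joint < alpha),
    fdr = sum(one$sig_fdr), bonferroni = sum(one$sig_bonf))
}

#' Run the two-stage environment-wide association scan
#'
#' Stage 1 fits every exposure in the discovery set (75% by default) and
#' adjusts the per-variable joint p-values across all tested variables;
#' stage 2 refits only the discovery-significant variables in the held-out
#' test set and adjusts across that subset only. Both FDR and Bonferroni
#' significance are reported at both stages. Continuous exposures are first
#' screened for a quadratic term in the discovery set; a significant term is
#' kept in both stages.
#'
#' @param data Harmonized, QC-filtered cohort with scored outcome and
#'   imputed covariates.
#' @param dictionary `enwas_dictionary` describing the exposures.
#' @param config A [scan_config()].
#' @param variables Exposure columns to test (default: all dictionary
#'   variables present in `data`).
#' @return An `enwas_scan`: `results` (one row per contrast, both stages)
#'   and `report` (per-stage and per-domain counts, skipped variables).
#' @export
run_enwas <- function(data, dictionary, config = scan_config(),
                      variables = NULL) {
  variables <- variables %||% intersect(names(dictionary), names(data))
  halves <- split_cohort(data, config$split_fraction, config$seed)
  disc <- halves$discovery
  covs <- covariate_sets()[[config$covariate_set]]
  if (config$sensitivity == "gsi_adjusted") covs <- union(covs, "gsi")
  cov_df <- drop_constant_cols(disc[, intersect(covs, names(disc)), drop = FALSE])
  quad_retained <- character()
  quad_p <- stats::setNames(rep(NA_real_, length(variables)), variables)
  if (isTRUE(config$quadratic_screen)) {
    for (v in variables) {
      r <- dictionary[[v]]
      if (is.null(r) || r$var_type != "continuous") next
      sq <- tryCatch(
        screen_quadratic(disc[[config$outcome_col]], disc[[v]], cov_df,
                         alpha = config$alpha, name = v),
        error = function(e) NULL)
      if (!is.null(sq)) {
        quad_p[v] <- sq$p_quadratic
        if (sq$retain) quad_retained <- c(quad_retained, v)
      }
    }
  }
  s1 <- fit_stage(disc, variables, dictionary, config, "discovery", quad_retained)
  if (is.null(s1$results)) {
    stop_enwas("no exposure could be fitted in the discovery set", "enwas_config_error")
  }
  s1$results <- adjust_stage(s1$results, config$alpha, config$correction)
  scr <- quad_p[s1$results$variable]
  s1$results$p_quadratic <- ifelse(is.na(s1$results$p_quadratic), unname(scr),
                                   s1$results$p_quadratic)
  carried <- unique(s1$results$variable[
    if (config$correction == "bonferroni") s1$results$sig_bonf else s1$results$sig_fdr])
  s2 <- list(results = NULL, skipped = list())
  if (length(carried)) {
    s2 <- fit_stage(halves$test, carried, dictionary, config, "test", quad_retained)
    if (!is.null(s2$results)) {
      s2$results <- adjust_stage(s2$results, config$alpha, config$correction)
    }
  }
  results <- rbind(s1$results, s2$results)
  rownames(results) <- NULL
  dom <- vapply(results$variable, function(v) {
    r <- dictionary[[v]]
    if (is.null(r)) NA_character_ else r$domain
  }, character(1))
  per_domain <- table(domain = dom[!duplicated(results$variable) &
                                     results$stage == "discovery"])
  surviving <- if (!is.null(s2$results)) {
    unique(s2$results$variable[
      if (config$correction == "bonferroni") s2$results$sig_bonf else s2$results$sig_fdr])
  } else character()
  report <- structure(
    list(stages = rbind(discovery = stage_counts(s1$results, config$alpha),
                        test = stage_counts(s2$results, config$alpha)),
         per_domain = per_domain,
         carried_forward = carried,
         surviving = surviving,
         quadratic_retained = quad_retained,
         skipped = c(s1$skipped, s2$skipped),
         config = config),
    class = "enwas_report")
  structure(list(results = results, report = report), class = "enwas_scan")
}

#' Sensitivity reruns of the scan
#'
#' `dutch_only` restricts to children of two ethnically Dutch parents and,
#' because that subset is small, drops the split: the main-analysis hits are
#' re-assessed in one combined set. `exclude_asd` drops diagnosed subjects
#' and reruns the full two-stage scan. `gsi_adjusted` adds the maternal GSI
#' score to the covariates and removes the parental-health and
#' parental-psychopathology domains from the tested set.
#'
#' @param data,dictionary,config As in [run_enwas()].
#' @param mode `"dutch_only"`, `"exclude_asd"`, or `"gsi_adjusted"`.
#' @param main_hits Variables to re-assess under `dutch_only` (typically the
#'   main scan's surviving set).
#' @return An `enwas_scan` (single-stage for `dutch_only`).
#' @export
run_sensitivity <- function(data, dictionary, config = scan_config(),
                            mode = c("dutch_only", "exclude_asd", "gsi_adjusted"),
                            main_hits = NULL) {
  mode <- match.arg(mode)
  config$sensitivity <- mode
  if (mode == "dutch_only") {
    if (!"dutch_parents" %in% names(data)) {
      stop_enwas("dutch_only requires a 'dutch_parents' indicator column",
                 "enwas_config_error")
    }
    sub <- data[!is.na(data$dutch_parents) & data$dutch_parents, , drop = FALSE]
    vars <- main_hits %||% intersect(names(dictionary), names(sub))
    st <- fit_stage(sub, vars, dictionary, config, "combined")
    if (is.null(st$results)) {
      stop_enwas("no exposure could be fitted in the Dutch-only subset",
                 "enwas_config_error")
    }
    st$results <- adjust_stage(st$results, config$alpha, config$correction)
    surv <- unique(st$results$variable[st$results$sig_fdr])
    report <- structure(
      list(stages = rbind(combined = stage_counts(st$results, config$alpha)),
           per_domain = table(domain = st$results$domain[!duplicated(st$results$variable)]),
           carried_forward = vars, surviving = surv,
           quadratic_retained = character(), skipped = st$skipped,
           config = config),
      class = "enwas_report")
    return(structure(list(results = st$results, report = report),
                     class = "enwas_scan"))
  }
  if (mode == "exclude_asd") {
    if (!"asd_dx" %in% names(data)) {
      stop_enwas("exclude_asd requires an 'asd_dx' indicator column",
                 "enwas_config_error")
    }
    sub <- data[is.na(data$asd_dx) | data$asd_dx == 0, , drop = FALSE]
    return(run_enwas(sub, dictionary, config))
  }
  # gsi_adjusted
  if (!"gsi" %in% names(data)) {
    stop_enwas("gsi_adjusted requires a 'gsi' column", "enwas_config_error")
  }
  doms <- vapply(dictionary, function(r) r$domain, character(1))
  vars <- names(dictionary)[!doms %in% c("parental_health",
                                         "parental_psychopathology")]
  run_enwas(data, dictionary, config, variables = intersect(vars, names(data)))
}

#' Write scan results as TSV
#'
#' One row per contrast: variable, domain, var_type, contrast, n, B,
#' B_intercept, CI_low, CI_high, p_joint, p_quadratic, stage, p_fdr, p_bonf,
#' sig_fdr, sig_bonf.
#'
#' @param scan An `enwas_scan`.
#' @param path Output path.
#' @export
write_results <- function(scan, path) {
  utils::write.table(scan$results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.enwas_scan <- function(x, ...) {
  cat("<enwas_scan>\n")
  print(x$report$stages)
  cat(sprintf("surviving variables: %d\n", length(x$report$surviving)))
  invisible(x)
}
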