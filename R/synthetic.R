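# Synthetic cohort generator. Emulates the structure of a prenatal birth
# cohort used for an environment-wide association scan: ~920 mixed-type
# exposure variables in 10 topical domains with latent-factor block
# correlation, questionnaire-wave structural missingness, covariates with
# literature-scale effects, an 18-item SRS outcome whose mean item score is
# right-skewed, and optional planted exposure effects on the square-root
# outcome scale. Everything is deterministic given the spec seed.

#' Describe a synthetic cohort
#'
#' Defaults reproduce the structure of the motivating study population:
#' 3891 subjects, 920 exposures across ten domains, within-domain
#' latent-factor loading 0.6 (pairwise correlation 0.36), a mean SRS item
#' score with mean 0.22 and SD 0.23, and covariate effects at the magnitudes
#' reported for the standard epidemiological covariates.
#'
#' @param n_subjects Number of subjects.
#' @param domains Named integer vector: variables per domain.
#' @param loading Latent-factor loading shared by variables of one domain.
#' @param type_mix Proportions of continuous / ordered / unordered exposures.
#' @param n_conditional Number of conditional parent-child question pairs.
#' @param dk_rate Share of categorical variables carrying a "Do not know"
#'   option; `dk_answer_rate` is the share of answers using it.
#' @param dk_answer_rate See `dk_rate`.
#' @param n_waves Number of questionnaire waves over which exposures are
#'   spread; a subject misses a whole wave with `wave_missing_rate`.
#' @param wave_missing_rate,item_missing_rate Structural (per wave) and MCAR
#'   (per cell) exposure missingness rates.
#' @param srs_item_missing_rate MCAR rate on the 18 outcome items.
#' @param covariate_missing_rate MCAR rate on imputable covariates.
#' @param outcome_mean,outcome_sd Target mean/SD of the mean SRS item score.
#' @param noise_shape Gamma shape of the right-skewed outcome noise.
#' @param gsi_effect Direct effect of the GSI psychopathology score on the
#'   square-root outcome.
#' @param planted_effects Named numeric: exposure name -> effect B on the
#'   square-root outcome scale (per SD for continuous exposures, per level
#'   step for ordered, for the last level of unordered).
#' @param confounded_ethnicity Names of exposures shifted by nonwestern
#'   ethnicity but given no direct outcome effect (for the Dutch-only
#'   sensitivity contract).
#' @param asd_flag_rate Prevalence of the ASD diagnosis flag.
#' @param seed RNG seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 3891,
                           domains = c(parental_health = 260,
                                       parental_psychopathology = 134,
                                       sociodemographic = 80,
                                       lifestyle_life_events = 70,
                                       nutrition_toxins = 120,
                                       family_rearing = 123,
                                       maternal_expectations = 20,
                                       maternal_biomarkers = 60,
                                       perinatal_obstetric = 33,
                                       cord_blood_biomarkers = 20),
                           loading = 0.6,
                           type_mix = c(continuous = 0.40,
                                        ordered = 0.45,
                                        unordered = 0.15),
                           n_conditional = 5L,
                           dk_rate = 0.10, dk_answer_rate = 0.03,
                           n_waves = 4L, wave_missing_rate = 0.10,
                           item_missing_rate = 0.05,
                           srs_item_missing_rate = 0.02,
                           covariate_missing_rate = 0.05,
                           outcome_mean = 0.22, outcome_sd = 0.23,
                           noise_shape = 0.5,
                           gsi_effect = 0.05,
                           planted_effects = numeric(),
                           confounded_ethnicity = character(),
                           asd_flag_rate = 0.01,
                           seed = 1L) {
  if (any(domains <= 0)) stop_enwas("domain counts must be positive", "enwas_spec_error")
  if (outcome_sd^2 > 2 * outcome_mean^2) {
    stop_enwas("outcome_sd too large for outcome_mean under the square-root model",
               "enwas_spec_error")
  }
  structure(list(n_subjects = n_subjects, domains = domains, loading = loading,
                 type_mix = type_mix / sum(type_mix),
                 n_conditional = as.integer(n_conditional),
                 dk_rate = dk_rate, dk_answer_rate = dk_answer_rate,
                 n_waves = as.integer(n_waves),
                 wave_missing_rate = wave_missing_rate,
                 item_missing_rate = item_missing_rate,
                 srs_item_missing_rate = srs_item_missing_rate,
                 covariate_missing_rate = covariate_missing_rate,
                 outcome_mean = outcome_mean, outcome_sd = outcome_sd,
                 noise_shape = noise_shape, gsi_effect = gsi_effect,
                 planted_effects = planted_effects,
                 confounded_ethnicity = confounded_ethnicity,
                 mediation = NULL,
                 asd_flag_rate = asd_flag_rate, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Solve for the square-root-scale intercept mu and noise scale s such that
# S = eta^2 has the target sample mean and SD, where eta floors the
# baseline at 0 before adding the (shifted, mostly nonnegative) planted
# part and caps at sqrt(3). mu is monotone in the mean at fixed s; s is
# monotone in the SD.
calibrate_outcome <- function(csys, planted, e0, target_mean, target_sd) {
  eta_at <- function(mu, s) {
    pmax(pmin(pmax(mu + csys + s * e0, 0) + planted, sqrt(3)), 0)
  }
  mean_at <- function(mu, s) mean(eta_at(mu, s)^2)
  sd_at <- function(s) {
    mu <- stats::uniroot(function(m) mean_at(m, s) - target_mean,
                         c(-10, 5), tol = 1e-8)$root
    c(mu = mu, sd = stats::sd(eta_at(mu, s)^2))
  }
  lo <- 0.01
  hi <- 1.5
  if (sd_at(lo)["sd"] >= target_sd) {
    # systematic variation alone already reaches the target spread
    res <- sd_at(lo)
    return(list(mu = unname(res["mu"]), s = lo))
  }
  if (sd_at(hi)["sd"] <= target_sd) {
    res <- sd_at(hi)
    return(list(mu = unname(res["mu"]), s = hi))
  }
  s <- stats::uniroot(function(x) sd_at(x)["sd"] - target_sd, c(lo, hi),
                      tol = 1e-6)$root
  res <- sd_at(s)
  list(mu = unname(res["mu"]), s = s)
}

# Deterministic variable layout: names, domains, types, level counts, waves.
variable_layout <- function(spec) {
  doms <- rep(names(spec$domains), times = spec$domains)
  m <- length(doms)
  idx <- stats::ave(seq_len(m), doms, FUN = seq_along)
  nm <- paste0(abbreviate(doms, 6), "_v", sprintf("%03d", idx))
  # quota-interleaved type assignment so every domain holds every type
  pool <- c("continuous", "ordered_categorical", "unordered_categorical")
  mix <- spec$type_mix[c("continuous", "ordered", "unordered")]
  cnt <- c(0, 0, 0)
  types <- character(m)
  for (i in seq_len(m)) {
    pick <- which.max(mix * i - cnt)
    types[i] <- pool[pick]
    cnt[pick] <- cnt[pick] + 1
  }
  k <- integer(m)
  k[types == "ordered_categorical"] <- rep_len(3:6, sum(types == "ordered_categorical"))
  k[types == "unordered_categorical"] <- rep_len(3:5, sum(types == "unordered_categorical"))
  data.frame(name = nm, domain = doms, var_type = types, k = k,
             wave = (seq_len(m) - 1L) %% spec$n_waves + 1L,
             stringsAsFactors = FALSE)
}

#' Generate a data dictionary for a synthetic cohort
#'
#' Emits a valid dictionary over the spec's domains: typed variables (ordered
#' levels `L1 < ... < Lk`, unordered labels `catA ...`), a configurable
#' number of conditional parent-child pairs (Yes/No parent, gate "Yes"), and
#' "Do not know" options on a share of categorical variables, so every
#' harmonization path is exercised.
#'
#' @param spec A [synthetic_spec()].
#' @return An `enwas_dictionary`.
#' @export
generate_dictionary <- function(spec) {
  lay <- variable_layout(spec)
  with_seed(spec$seed, {
    cat_idx <- which(lay$var_type != "continuous")
    dk_idx <- sort(sample(cat_idx, round(spec$dk_rate * length(cat_idx))))
    # conditional pairs: parent becomes a Yes/No question, child the next
    # categorical variable in the same domain
    pair_parent <- integer(0)
    pair_child <- integer(0)
    if (spec$n_conditional > 0L) {
      for (i in cat_idx) {
        if (length(pair_parent) >= spec$n_conditional) break
        j <- cat_idx[cat_idx > i & lay$domain[cat_idx] == lay$domain[i]]
        j <- setdiff(j, c(pair_parent, pair_child))
        if (i %in% c(pair_parent, pair_child) || length(j) == 0L) next
        pair_parent <- c(pair_parent, i)
        pair_child <- c(pair_child, j[1L])
      }
    }
    recs <- vector("list", nrow(lay))
    for (i in seq_len(nrow(lay))) {
      type <- lay$var_type[i]
      if (i %in% pair_parent) {
        levels <- c("No", "Yes")
        type <- "unordered_categorical"
      } else if (type == "ordered_categorical") {
        levels <- paste0("L", seq_len(lay$k[i]))
      } else if (type == "unordered_categorical") {
        levels <- paste0("cat", LETTERS[seq_len(lay$k[i])])
      } else {
        levels <- NULL
      }
      dk <- if (i %in% dk_idx && !i %in% pair_parent) "Do not know" else character()
      parent <- NULL
      gate <- NULL
      ci <- match(i, pair_child)
      if (!is.na(ci)) {
        parent <- lay$name[pair_parent[ci]]
        gate <- "Yes"
      }
      recs[[i]] <- variable_record(lay$name[i], lay$domain[i], type,
                                   levels = levels, parent = parent,
                                   parent_gate = gate, dont_know_labels = dk)
    }
    enwas_dictionary(recs)
  })
}

#' Generate a synthetic cohort table
#'
#' Draws a subjects-by-variables table from the spec: one latent factor per
#' domain induces within-domain correlation `loading^2`; continuous
#' exposures are the latent-plus-noise scores, ordered/unordered exposures
#' threshold them at random category probabilities; conditional children are
#' structurally missing unless the parent gate opens; whole questionnaire
#' waves drop out per subject; covariates, an ASD flag and the 18 SRS items
#' are appended. The mean SRS item score is built on the square-root scale
#' (intercept + covariate effects + planted effects + right-skewed noise,
#' floored at zero and squared), so the scan's modeling assumption holds in
#' the generator by construction.
#'
#' @param spec A [synthetic_spec()].
#' @return An `enwas_cohort`: list with `data`, `dictionary`, and `truth`
#'   (planted/direct effects, mediation wiring, calibration constants).
#' @export
generate_cohort <- function(spec) {
  dictionary <- generate_dictionary(spec)
  lay <- variable_layout(spec)
  n <- spec$n_subjects
  m <- nrow(lay)
  planted <- spec$planted_effects
  if (length(planted) && !all(names(planted) %in% lay$name)) {
    stop_enwas("planted_effects refer to unknown variables", "enwas_spec_error")
  }
  if (length(spec$confounded_ethnicity) &&
      !all(spec$confounded_ethnicity %in% lay$name)) {
    stop_enwas("confounded_ethnicity refers to unknown variables", "enwas_spec_error")
  }
  with_seed(spec$seed + 7919L, {
    ## covariates -----------------------------------------------------------
    maternal_age <- stats::rnorm(n, 31.36, 4.46)
    child_sex <- sample(c("girl", "boy"), n, TRUE, c(0.505, 0.495))
    maternal_education <- sample(c("low", "medium", "high"), n, TRUE,
                                 c(0.05, 0.36, 0.59))
    maternal_ethnicity <- sample(c("Dutch", "OtherWestern", "NonWestern"), n,
                                 TRUE, c(0.68, 0.09, 0.23))
    parity <- sample(0:2, n, TRUE, c(0.61, 0.29, 0.10))
    birth_year <- sample(2002:2006, n, TRUE, c(0.092, 0.283, 0.32, 0.297, 0.008))
    age_srs <- 6.10 - 0.25 * (birth_year - 2004) + stats::rnorm(n, 0, 0.35)
    gestational_age <- stats::rnorm(n, 39.93, 1.70)
    birth_weight <- 3447 + 0.61 * (559 / 1.70) * (gestational_age - 39.93) +
      stats::rnorm(n, 0, 559 * sqrt(1 - 0.61^2))
    paternal_dutch <- stats::rbinom(n, 1,
                                    ifelse(maternal_ethnicity == "Dutch", 0.85, 0.10)) == 1
    dutch_parents <- maternal_ethnicity == "Dutch" & paternal_dutch

    ## exposures ------------------------------------------------------------
    factors <- matrix(stats::rnorm(n * length(spec$domains)), n,
                      dimnames = list(NULL, names(spec$domains)))
    lam <- spec$loading
    z <- factors[, lay$domain, drop = FALSE] * lam +
      matrix(stats::rnorm(n * m), n, m) * sqrt(1 - lam^2)
    colnames(z) <- lay$name
    nw <- maternal_ethnicity == "NonWestern"
    for (v in spec$confounded_ethnicity) z[, v] <- z[, v] + 1.0 * nw

    values <- vector("list", m)
    names(values) <- lay$name
    x_code <- matrix(0, n, m, dimnames = list(NULL, lay$name))
    for (i in seq_len(m)) {
      r <- dictionary[[lay$name[i]]]
      if (is.null(r$levels)) {
        values[[i]] <- z[, i]
        x_code[, i] <- z[, i]
      } else {
        k <- length(setdiff(r$levels, "Do not know"))
        p <- stats::rgamma(k, 1) + 0.3
        cuts <- stats::qnorm((cumsum(p) / sum(p))[-k])
        bin <- findInterval(z[, i], cuts) + 1L
        values[[i]] <- setdiff(r$levels, "Do not know")[bin]
        x_code[, i] <- if (r$var_type == "ordered_categorical") bin - 1L
                       else as.numeric(bin == k)
      }
    }

    ## outcome on the square-root scale -------------------------------------
    gsi <- 0.6 * factors[, "parental_psychopathology"] +
      0.8 * stats::rnorm(n)
    med <- spec$mediation
    direct <- planted
    if (!is.null(med)) {
      B <- planted[[med$exposure]]
      if (spec$gsi_effect == 0) {
        stop_enwas("mediation requires a nonzero gsi_effect", "enwas_spec_error")
      }
      gsi <- gsi + (med$share * B / spec$gsi_effect) * x_code[, med$exposure]
      direct[[med$exposure]] <- (1 - med$share) * B
    }
    eff <- spec$gsi_effect * gsi +
      -0.007 * (maternal_age - 31.36) +
      c(low = 0.158, medium = 0.053, high = 0)[maternal_education] +
      c(Dutch = 0, OtherWestern = -0.005, NonWestern = 0.097)[maternal_ethnicity] +
      c(girl = 0, boy = 0.063)[child_sex] +
      0.001 * parity +
      c(`2002` = 0, `2003` = 0, `2004` = 0.019, `2005` = 0.026,
        `2006` = 0.026)[as.character(birth_year)] +
      -1.2e-5 * (birth_weight - 3447) +
      -0.003 * (gestational_age - 39.93)
    eff <- unname(eff)
    # Planted contributions are shifted to be nonnegative wherever the
    # exposure coding is bounded (ordered scores, indicators); the shift is
    # a constant absorbed by the calibrated intercept. The outcome floor
    # below is then applied to the baseline (intercept + covariates +
    # noise) before adding planted terms, so planted effects on bounded
    # codings never interact with the floor and their recovery is exactly
    # linear. Continuous planted codes are unbounded below; their rare
    # left-tail excursions still meet the final floor.
    planted_part <- numeric(n)
    for (v in names(direct)) {
      B <- direct[[v]]
      xc <- x_code[, v]
      r <- dictionary[[v]]
      if (!is.null(r$levels) && B < 0) {
        xc <- xc - max(length(setdiff(r$levels, "Do not know")) - 1L, 1L)
      }
      planted_part <- planted_part + B * xc
    }
    # calibration: mean item score S = eta^2; the intercept and the noise
    # scale are solved numerically so the realized S hits the target
    # mean/SD (the gamma noise is skewed, so closed-form normal moment
    # matching would miss the SD). Calibration uses an independent
    # reference noise draw so neither parameter is a function of the noise
    # realizations entering the outcome; neither touches the planted or
    # covariate coefficients.
    kshape <- spec$noise_shape
    csys <- eff - mean(eff)
    n_cal <- max(n, 5000L)
    e_cal <- (stats::rgamma(n_cal, kshape) - kshape) / sqrt(kshape)
    cal <- calibrate_outcome(rep_len(csys, n_cal), rep_len(planted_part, n_cal),
                             e_cal, spec$outcome_mean, spec$outcome_sd)
    mu_eta <- cal$mu
    s_noise <- cal$s
    e0 <- (stats::rgamma(n, kshape) - kshape) / sqrt(kshape)  # unit, skewed
    eta <- pmax(pmin(pmax(mu_eta + csys + s_noise * e0, 0) + planted_part,
                     sqrt(3)), 0)
    S <- eta^2

    ## SRS items ------------------------------------------------------------
    # 18 integer items can only encode mean scores on a 1/18 grid; choose
    # the item total stochastically between the two bracketing grid points
    # with the probability that makes sqrt(total/18) conditionally unbiased
    # for eta = sqrt(S) - the scale the scan models - so quantization adds
    # noise but no systematic slope distortion.
    a <- pmin(floor(18 * S), 53)
    ya <- sqrt(a / 18)
    yb <- sqrt((a + 1) / 18)
    p_up <- pmin(pmax((eta - ya) / (yb - ya), 0), 1)
    total <- a + (stats::runif(n) < p_up)
    q <- total %/% 18L
    rem <- total %% 18L
    items <- matrix(q, n, 18)
    offset <- (seq_len(n) - 1L) %% 18L
    for (j in 1:18) {
      pos <- (j - 1L - offset) %% 18L
      items[, j] <- items[, j] + (pos < rem)
    }
    items[matrix(stats::runif(n * 18) < spec$srs_item_missing_rate, n, 18)] <- NA
    colnames(items) <- paste0("srs_item_", 1:18)

    ## missingness on exposures and covariates ------------------------------
    wave_out <- matrix(stats::runif(n * spec$n_waves) < spec$wave_missing_rate,
                       n, spec$n_waves)
    for (i in seq_len(m)) {
      drop <- wave_out[, lay$wave[i]] |
        stats::runif(n) < spec$item_missing_rate
      values[[i]][drop] <- NA
    }
    # structural missingness + "Do not know" answers
    for (nm in names(dictionary)) {
      r <- dictionary[[nm]]
      if (!is.null(r$parent)) {
        gate_open <- !is.na(values[[r$parent]]) & values[[r$parent]] == r$parent_gate
        values[[nm]][!gate_open] <- NA
      }
      if (length(r$dont_know_labels)) {
        obs <- which(!is.na(values[[nm]]))
        hit <- obs[stats::runif(length(obs)) < spec$dk_answer_rate]
        values[[nm]][hit] <- r$dont_know_labels[1L]
      }
    }
    covs <- data.frame(maternal_age = maternal_age,
                       maternal_education = maternal_education,
                       parity = parity, gestational_age = gestational_age,
                       birth_weight = birth_weight, gsi = gsi)
    for (v in names(covs)) {
      covs[[v]][stats::runif(n) < spec$covariate_missing_rate] <- NA
    }

    data <- cbind(
      data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                 age_srs = age_srs, child_sex = child_sex,
                 maternal_ethnicity = maternal_ethnicity,
                 birth_year = as.character(birth_year),
                 dutch_parents = dutch_parents,
                 asd_dx = stats::rbinom(n, 1, spec$asd_flag_rate),
                 stringsAsFactors = FALSE),
      covs,
      as.data.frame(values, optional = TRUE, stringsAsFactors = FALSE),
      as.data.frame(items))
    structure(list(data = data, dictionary = dictionary,
                   truth = list(planted = planted, direct = direct,
                                mediation = med,
                                confounded = spec$confounded_ethnicity,
                                mu_eta = mu_eta, noise_sd = s_noise,
                                within_domain_cor = lam^2),
                   spec = spec),
              class = "enwas_cohort")
  })
}

#' Reroute part of a planted effect through a mediator
#'
#' Rewires the outcome model so that `share` of the named exposure's total
#' effect flows through the GSI mediator (exposure -> GSI -> outcome) while
#' the total effect is unchanged; adjusting for GSI then recovers only the
#' direct part, `(1 - share) * B`.
#'
#' @param spec A [synthetic_spec()] with a planted effect on `exposure`.
#' @param exposure Name of the planted exposure.
#' @param share Proportion of the effect mediated, in `[0, 1]`.
#' @param mediator Mediator name (only `"gsi"` is wired).
#' @return The modified spec (unchanged when `share = 0`).
#' @export
plant_mediation <- function(spec, exposure, share, mediator = "gsi") {
  if (share < 0 || share > 1) {
    stop_enwas("mediated share must be in [0, 1]", "enwas_spec_error")
  }
  if (!exposure %in% names(spec$planted_effects)) {
    stop_enwas(sprintf("no planted effect on '%s' to mediate", exposure),
               "enwas_spec_error")
  }
  if (!identical(mediator, "gsi")) {
    stop_enwas("only the GSI mediator is supported", "enwas_spec_error")
  }
  if (share == 0) return(spec)
  spec$mediation <- list(exposure = exposure, share = share, mediator = mediator)
  spec
}

#' Write a synthetic cohort to disk
#'
#' Produces `data.tsv`, `dictionary.yaml` and `truth.json` (the planted
#' effects, for oracle tests) in `out_dir`.
#'
#' @param cohort An `enwas_cohort` from [generate_cohort()].
#' @param out_dir Output directory (created if needed).
#' @export
write_synthetic <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(cohort$data, file.path(out_dir, "data.tsv"))
  write_dictionary(cohort$dictionary, file.path(out_dir, "dictionary.yaml"))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
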