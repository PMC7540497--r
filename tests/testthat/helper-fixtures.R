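# Shared fixtures: built in code, deterministic.

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# adjusted p_i = min over j with p_j >= p_i of min(1, m * p_(j) / rank_j),
# computed without stats::p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * ps[i] / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# smoking-style conditional pair: "Have you ever smoked?" gating
# "Do you still smoke?"
smoking_fixture <- function() {
  parent <- variable_record("ever_smoked", "lifestyle_life_events",
                            "unordered_categorical", levels = c("No", "Yes"))
  child <- variable_record("still_smokes", "lifestyle_life_events",
                           "unordered_categorical",
                           levels = c("Still", "Quit"),
                           parent = "ever_smoked", parent_gate = "Yes")
  pv <- c("No", "Yes", "Yes", NA, "Yes", "No")
  cv <- c(NA, "Still", "Quit", NA, NA, NA)
  list(parent = parent, child = child, parent_values = pv, child_values = cv)
}

# expand per-level counts into a value vector
values_from_counts <- function(counts) {
  rep(names(counts), times = counts)
}

# small ten-domain spec for pipeline tests
small_domains <- c(parental_health = 4, parental_psychopathology = 4,
                   sociodemographic = 3, lifestyle_life_events = 3,
                   nutrition_toxins = 3, family_rearing = 3,
                   maternal_expectations = 2, maternal_biomarkers = 3,
                   perinatal_obstetric = 2, cord_blood_biomarkers = 2)

small_spec <- function(n = 500, seed = 1, n_conditional = 2, ...) {
  synthetic_spec(n_subjects = n, domains = small_domains,
                 n_conditional = n_conditional, seed = seed, ...)
}

imputable_covariates <- c("maternal_age", "maternal_education", "parity",
                          "gestational_age", "birth_weight", "gsi")

# harmonize + QC + outcome + imputation, ready for run_enwas()
prepare_cohort <- function(coh, impute_seed = 99) {
  h <- harmonize_cohort(coh$data, coh$dictionary)
  qc <- qc_filter(h$data, names(h$dictionary))
  d <- add_srs_outcome(qc$data)
  d <- d[!d$srs_excluded & !is.na(d$y), , drop = FALSE]
  imp <- impute_covariates(d, imputable_covariates, outcome = "y",
                           seed = impute_seed)
  list(data = imp$data, dictionary = h$dictionary,
       variables = qc$variables)
}

# first continuous dictionary variables, one per domain
continuous_by_domain <- function(dictionary) {
  cont <- names(dictionary)[vapply(dictionary, function(r)
    r$var_type == "continuous", logical(1))]
  doms <- vapply(dictionary[cont], function(r) r$domain, character(1))
  cont[!duplicated(doms)]
}
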