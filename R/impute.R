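# Single imputation of missing covariate values by chained equations. Each
# covariate with missing entries gets a conditional model on all other
# covariates (plus, optionally, the outcome): a linear model for continuous
# covariates, and a linear model on integer category scores - with imputed
# draws snapped to the nearest observed level - for categoricals. One
# completed dataset is produced; exposures are never imputed.

#' Impute missing covariates by chained equations
#'
#' Starts from a mean/mode fill, then sweeps covariates in descending order
#' of missingness for `n_iter` iterations. Continuous covariates are imputed
#' as the conditional-model prediction plus a residual-scaled normal draw;
#' categorical covariates are modeled on integer scores and snapped back to
#' the nearest observed label. Observed values are never altered, and the
#' run is deterministic for a fixed seed.
#'
#' @param data Cohort data frame.
#' @param covariates Covariate column names to complete.
#' @param outcome Optional outcome column name used as a predictor.
#' @param n_iter Number of chained-equation sweeps (default 10).
#' @param seed RNG seed for the imputation draws.
#' @return List with the completed `data` and `model`: covariate list,
#'   per-covariate model type, iteration count, seed and a convergence
#'   `trace` (per-iteration mean absolute change of imputed values).
#' @export
impute_covariates <- function(data, covariates, outcome = NULL, n_iter = 10L,
                              seed = 1L) {
  if (n_iter < 1L) stop_enwas("n_iter must be >= 1", "enwas_config_error")
  missing_cov <- vapply(covariates, function(v) mean(is.na(data[[v]])), numeric(1))
  if (any(missing_cov == 1)) {
    stop_enwas(sprintf("covariate(s) fully missing: %s",
                       paste(covariates[missing_cov == 1], collapse = ", ")),
               "enwas_impute_error")
  }
  is_cat <- vapply(covariates, function(v)
    is.character(data[[v]]) || is.factor(data[[v]]) || is.logical(data[[v]]),
    logical(1))
  levs <- lapply(covariates, function(v)
    if (is.factor(data[[v]])) levels(data[[v]])
    else sort(unique(as.character(stats::na.omit(data[[v]])))))
  names(levs) <- names(is_cat) <- covariates

  # numeric working copy: categoricals as integer scores
  num <- data
  for (v in covariates[is_cat]) {
    num[[v]] <- match(as.character(data[[v]]), levs[[v]])
  }
  miss_idx <- lapply(covariates, function(v) which(is.na(num[[v]])))
  names(miss_idx) <- covariates
  todo <- covariates[vapply(miss_idx, length, integer(1)) > 0L]
  if (length(todo) == 0L) {
    return(list(data = data,
                model = list(covariates = covariates,
                             model_type = ifelse(is_cat, "multinomial_score", "linear"),
                             n_iter = 0L, seed = seed, trace = numeric())))
  }
  todo <- todo[order(-missing_cov[todo])]           # descending missingness
  preds_of <- function(v) c(setdiff(covariates, v),
                            if (!is.null(outcome)) outcome)
  # initial fill: observed mean (continuous) / modal score (categorical)
  for (v in todo) {
    obs <- num[[v]][-miss_idx[[v]]]
    fill <- if (is_cat[[v]]) as.numeric(modal_level(obs)) else mean(obs)
    num[[v]][miss_idx[[v]]] <- fill
  }
  trace <- numeric(n_iter)
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      delta <- 0
      n_imp <- 0L
      for (v in todo) {
        idx <- miss_idx[[v]]
        rhs <- preds_of(v)
        df <- num[, c(v, rhs), drop = FALSE]
        ok <- stats::complete.cases(df[, rhs, drop = FALSE])
        fit <- stats::lm(stats::reformulate(rhs, response = v),
                         data = df[ok & !seq_len(nrow(df)) %in% idx, , drop = FALSE])
        pred <- stats::predict(fit, newdata = df[idx, rhs, drop = FALSE])
        sigma <- summary(fit)$sigma
        if (!is.finite(sigma)) sigma <- 0
        draw <- pred + stats::rnorm(length(pred), 0, sigma)
        if (is_cat[[v]]) {
          draw <- pmin(pmax(round(draw), 1L), length(levs[[v]]))
          # snap to levels actually observed for this covariate
          obs_codes <- sort(unique(num[[v]][-idx]))
          draw <- obs_codes[pmax(1L, findInterval(draw, obs_codes,
                                                  all.inside = TRUE))]
        }
        draw[is.na(draw)] <- num[[v]][idx][is.na(draw)]   # unpredictable rows keep fill
        delta <- delta + sum(abs(num[[v]][idx] - draw))
        n_imp <- n_imp + length(idx)
        num[[v]][idx] <- draw
      }
      trace[it] <- delta / n_imp
    }
  })
  out <- data
  for (v in todo) {
    imputed <- num[[v]][miss_idx[[v]]]
    if (is_cat[[v]]) {
      lab <- levs[[v]][imputed]
      if (is.factor(data[[v]])) {
        out[[v]][miss_idx[[v]]] <- factor(lab, levels = levs[[v]])
      } else if (is.logical(data[[v]])) {
        out[[v]][miss_idx[[v]]] <- as.logical(lab)
      } else {
        out[[v]][miss_idx[[v]]] <- lab
      }
    } else {
      out[[v]][miss_idx[[v]]] <- imputed
    }
  }
  list(data = out,
       model = list(covariates = covariates,
                    model_type = stats::setNames(
                      ifelse(is_cat, "multinomial_score", "linear"), covariates),
                    n_iter = as.integer(n_iter), seed = seed, trace = trace))
}
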