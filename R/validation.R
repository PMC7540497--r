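# Operating characteristics of the two-stage design under the complete
# null. With independent exposures and an independent outcome, BH FDR at
# alpha rejects anything at all with probability alpha (FDR equals FWER
# under the complete null), so a single discovery stage has a ~5% chance of
# >= 1 false positive over 920 tests and the discovery+test cascade a
# ~0.25% (= alpha^2) chance. The kernel uses the closed-form
# simple-regression p-value; its equality with the full lm-based scan
# kernel on identical data is asserted by a regression test.

#' Closed-form per-variable simple-regression p-values
#'
#' Two-sided t-test p-values for the slope of `y` on each column of `X`
#' (no covariates), computed from the correlation in closed form; equal to
#' `summary(lm(y ~ x))` coefficient p-values.
#'
#' @param X Numeric matrix, subjects x variables.
#' @param y Outcome vector.
#' @return Vector of p-values, one per column.
#' @export
simple_scan_pvalues <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  sxy <- crossprod(X, yc)[, 1L]
  sxx <- colSums(X^2) - n * colMeans(X)^2
  r <- sxy / sqrt(sxx * sum(yc^2))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), n - 2)
}

# one replicate under the global null: does anything survive?
null_rep <- function(m, n, alpha, stages, split_fraction) {
  X <- matrix(stats::rnorm(n * m), n, m)
  y <- stats::rnorm(n)
  if (stages == 1L) {
    p <- simple_scan_pvalues(X, y)
    return(any(adjust_pvalues(p, "fdr_bh") <= alpha))
  }
  idx <- sort(sample.int(n, round(n * split_fraction)))
  p1 <- simple_scan_pvalues(X[idx, , drop = FALSE], y[idx])
  hit <- which(adjust_pvalues(p1, "fdr_bh") <= alpha)
  if (length(hit) == 0L) return(FALSE)
  p2 <- simple_scan_pvalues(X[-idx, hit, drop = FALSE], y[-idx])
  any(adjust_pvalues(p2, "fdr_bh") <= alpha)
}

binom_ci <- function(k, n) {
  as.numeric(stats::binom.test(k, n)$conf.int)
}

#' Estimate the family-wise false-positive rate of the scan design
#'
#' Simulates replicate null cohorts (independent standard-normal exposures,
#' outcome independent of all of them), runs the scan kernel with BH FDR at
#' `alpha` - one stage, or the full discovery/test cascade - and reports the
#' share of replicates with at least one surviving variable, with an exact
#' binomial 95% CI.
#'
#' @param m Number of exposure variables (default 920).
#' @param n Subjects per replicate.
#' @param alpha Significance level.
#' @param stages 1 (discovery only) or 2 (discovery + test).
#' @param n_reps Number of replicates.
#' @param seed RNG seed.
#' @param split_fraction Discovery share for the two-stage design.
#' @return An `enwas_sim_report` with `fwer`, `ci`, and the config echo.
#' @export
estimate_fwer <- function(m = 920L, n = 500L, alpha = 0.05, stages = 1L,
                          n_reps = 1000L, seed = 1L, split_fraction = 0.75) {
  if (n_reps < 1L) stop_enwas("n_reps must be >= 1", "enwas_config_error")
  if (!stages %in% 1:2) stop_enwas("stages must be 1 or 2", "enwas_config_error")
  hits <- with_seed(seed, {
    vapply(seq_len(n_reps),
           function(i) null_rep(m, n, alpha, stages, split_fraction),
           logical(1))
  })
  k <- sum(hits)
  structure(list(fwer = k / n_reps, ci = binom_ci(k, n_reps),
                 n_hits = k, n_reps = n_reps,
                 config = list(m = m, n = n, alpha = alpha, stages = stages,
                               correction = "fdr_bh",
                               split_fraction = split_fraction, seed = seed)),
            class = "enwas_sim_report")
}

#' Estimate two-stage power for planted effects
#'
#' Simulates cohorts in which `length(planted)` exposures carry linear
#' effects on the square-root-scale outcome (the remaining `m - k` are
#' null), runs the full discovery/test cascade, and reports per-effect
#' survival shares.
#'
#' @param planted Named or unnamed numeric vector of effects B (square-root
#'   outcome scale, per SD of exposure).
#' @param m Total number of exposures.
#' @param n Subjects per replicate.
#' @param alpha Significance level.
#' @param n_reps Number of replicates.
#' @param seed RNG seed.
#' @param split_fraction Discovery share.
#' @param sigma Residual SD of the outcome (default 0.268, the generator's
#'   calibrated square-root-scale noise).
#' @return An `enwas_sim_report` with per-effect `power` and binomial CIs.
#' @export
estimate_power <- function(planted, m = 920L, n = 3891L, alpha = 0.05,
                           n_reps = 200L, seed = 1L, split_fraction = 0.75,
                           sigma = 0.268) {
  if (n_reps < 1L) stop_enwas("n_reps must be >= 1", "enwas_config_error")
  k <- length(planted)
  surv <- matrix(FALSE, n_reps, k)
  with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      X <- matrix(stats::rnorm(n * m), n, m)
      y <- X[, seq_len(k), drop = FALSE] %*% planted + stats::rnorm(n, 0, sigma)
      idx <- sort(sample.int(n, round(n * split_fraction)))
      p1 <- simple_scan_pvalues(X[idx, , drop = FALSE], y[idx])
      hit <- which(adjust_pvalues(p1, "fdr_bh") <= alpha)
      if (length(hit) == 0L) next
      p2 <- simple_scan_pvalues(X[-idx, hit, drop = FALSE], y[-idx])
      ok <- hit[adjust_pvalues(p2, "fdr_bh") <= alpha]
      surv[rep, ] <- seq_len(k) %in% ok
    }
  })
  pow <- colMeans(surv)
  cis <- lapply(seq_len(k), function(j) binom_ci(sum(surv[, j]), n_reps))
  structure(list(power = stats::setNames(pow, names(planted)),
                 ci = cis, n_reps = n_reps,
                 config = list(m = m, n = n, alpha = alpha,
                               correction = "fdr_bh",
                               split_fraction = split_fraction, seed = seed,
                               sigma = sigma, planted = planted)),
            class = "enwas_sim_report")
}

#' @export
print.enwas_sim_report <- function(x, ...) {
  cat("<enwas_sim_report>\n")
  if (!is.null(x$fwer)) {
    cat(sprintf("FWER: %.4f (95%% CI %.4f-%.4f) over %d replicates\n",
                x$fwer, x$ci[1], x$ci[2], x$n_reps))
  }
  if (!is.null(x$power)) {
    cat("power:\n")
    print(x$power)
  }
  invisible(x)
}
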