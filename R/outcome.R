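# Outcome scoring for the 18-item short-form Social Responsiveness Scale
# (SRS). Items are parent-rated 0 ("never true") to 3 ("almost always
# true"). A subject's score is excluded when over 25% of items are missing;
# otherwise the mean item score is taken over nonmissing items, a weighted
# total (18 x mean) is kept for reporting, and the regression outcome is the
# square root of the mean item score (the raw distribution is right-skewed).

#' Score the 18-item SRS outcome
#'
#' @param items Data frame or matrix of 18 item columns, values in
#'   \{0,1,2,3\} or missing.
#' @param max_missing Maximum tolerated missing-item share (default 0.25;
#'   strict `>` excludes).
#' @return Data frame with one row per subject: `n_items_present`,
#'   `excluded`, `mean_item_score`, `weighted_total`, and the regression
#'   outcome `y = sqrt(mean_item_score)` (all score columns `NA` when
#'   excluded).
#' @export
score_srs <- function(items, max_missing = 0.25) {
  items <- as.matrix(items)
  n_items <- ncol(items)
  bad <- !is.na(items) & !items %in% 0:3
  if (any(bad)) {
    stop_enwas(sprintf("%d SRS item values outside {0,1,2,3}", sum(bad)),
               "enwas_outcome_error")
  }
  present <- rowSums(!is.na(items))
  excluded <- (n_items - present) / n_items > max_missing
  mean_item <- rowMeans(items, na.rm = TRUE)
  mean_item[present == 0L | excluded] <- NA_real_
  data.frame(n_items_present = present,
             excluded = excluded,
             mean_item_score = mean_item,
             weighted_total = n_items * mean_item,
             y = sqrt(mean_item))
}

#' Attach SRS-derived outcome columns to a cohort table
#'
#' @param data Cohort data frame.
#' @param item_prefix Prefix of the 18 item columns (default `"srs_item_"`).
#' @param max_missing Passed to [score_srs()].
#' @return `data` with `srs_mean`, `srs_weighted_total`, `srs_excluded` and
#'   `y` columns appended.
#' @export
add_srs_outcome <- function(data, item_prefix = "srs_item_", max_missing = 0.25) {
  cols <- grep(paste0("^", item_prefix), names(data), value = TRUE)
  if (length(cols) == 0L) {
    stop_enwas(sprintf("no columns match prefix '%s'", item_prefix),
               "enwas_outcome_error")
  }
  sc <- score_srs(data[, cols, drop = FALSE], max_missing)
  data$srs_mean <- sc$mean_item_score
  data$srs_weighted_total <- sc$weighted_total
  data$srs_excluded <- sc$excluded
  data$y <- sc$y
  data
}
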