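# Dataset-level exclusion cascade: near-constant variables, then subjects
# with excessive missingness, then variables still mostly missing. All three
# rules use strict inequalities ("more than 95%", "more than 60%", "over
# 50%"), so exact-boundary cases are retained.

filter_report <- function(step, threshold, dropped, before, after) {
  structure(list(step = step, threshold = threshold, dropped = dropped,
                 n_before = before, n_after = after),
            class = "enwas_filter_report")
}

#' Drop near-constant variables
#'
#' Removes every exposure whose modal answer (among nonmissing responses)
#' covers more than `constancy_threshold` of respondents; such variables
#' carry almost no information.
#'
#' @param data Cohort data frame.
#' @param variables Exposure column names to screen (others pass untouched).
#' @param constancy_threshold Maximum allowed modal share (default 0.95;
#'   strict `>` to drop).
#' @return List with the filtered `data` and a `report`.
#' @export
drop_low_information <- function(data, variables, constancy_threshold = 0.95) {
  if (nrow(data) == 0L) stop_enwas("empty cohort table", "enwas_qc_error")
  share <- vapply(variables, function(v) modal_share(data[[v]]), numeric(1))
  drop <- variables[!is.na(share) & share > constancy_threshold]
  # fully missing columns have no modal share; they fall to the 50% filter
  list(data = data[, !names(data) %in% drop, drop = FALSE],
       report = filter_report("constancy", constancy_threshold, drop,
                              length(variables), length(variables) - length(drop)))
}

#' Drop subjects with excessive missingness
#'
#' Removes subjects missing more than `subject_threshold` of the remaining
#' exposure variables. Run after [drop_low_information()]; the cascade order
#' is part of the contract.
#'
#' @param data Cohort data frame.
#' @param variables Remaining exposure column names.
#' @param subject_threshold Maximum allowed missing share per subject
#'   (default 0.60; strict `>` to drop).
#' @param id_col Subject-identifier column used in the report.
#' @return List with the filtered `data` and a `report`.
#' @export
drop_sparse_subjects <- function(data, variables, subject_threshold = 0.60,
                                 id_col = "subject_id") {
  miss <- rowMeans(is.na(data[, variables, drop = FALSE]))
  drop <- miss > subject_threshold
  ids <- if (id_col %in% names(data)) data[[id_col]][drop] else which(drop)
  list(data = data[!drop, , drop = FALSE],
       report = filter_report("subjects", subject_threshold, ids,
                              nrow(data), sum(!drop)))
}

#' Drop variables that remain mostly missing
#'
#' Removes exposures with more than `variable_threshold` missing data among
#' the retained subjects. Run last in the cascade.
#'
#' @param data Cohort data frame.
#' @param variables Remaining exposure column names.
#' @param variable_threshold Maximum allowed missing share per variable
#'   (default 0.50; strict `>` to drop).
#' @return List with the filtered `data` and a `report`.
#' @export
drop_sparse_variables <- function(data, variables, variable_threshold = 0.50) {
  miss <- vapply(variables, function(v) mean(is.na(data[[v]])), numeric(1))
  drop <- variables[miss > variable_threshold]
  list(data = data[, !names(data) %in% drop, drop = FALSE],
       report = filter_report("variables", variable_threshold, drop,
                              length(variables), length(variables) - length(drop)))
}

#' Run the full QC exclusion cascade
#'
#' Applies, in fixed order: the constancy filter (modal share > 95%), the
#' subject-missingness filter (> 60% missing exposures), and the
#' variable-missingness filter (> 50% missing). Thresholds are exposed so the
#' robustness sweep the design calls for can be run.
#'
#' @param data Cohort data frame.
#' @param variables Exposure column names.
#' @param constancy_threshold,subject_threshold,variable_threshold Cascade
#'   thresholds.
#' @param id_col Subject-identifier column.
#' @return List with filtered `data`, surviving `variables`, and `reports`
#'   (one per step, reconstructing every intermediate shape).
#' @export
qc_filter <- function(data, variables, constancy_threshold = 0.95,
                      subject_threshold = 0.60, variable_threshold = 0.50,
                      id_col = "subject_id") {
  s1 <- drop_low_information(data, variables, constancy_threshold)
  v1 <- intersect(variables, names(s1$data))
  s2 <- drop_sparse_subjects(s1$data, v1, subject_threshold, id_col)
  s3 <- drop_sparse_variables(s2$data, v1, variable_threshold)
  structure(list(data = s3$data,
                 variables = intersect(v1, names(s3$data)),
                 reports = list(constancy = s1$report, subjects = s2$report,
                                variables = s3$report)),
            class = "enwas_qc")
}

#' Serialize a QC report to JSON
#'
#' @param qc Result of [qc_filter()].
#' @param path Output path.
#' @export
write_qc_report <- function(qc, path) {
  jsonlite::write_json(lapply(qc$reports, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
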