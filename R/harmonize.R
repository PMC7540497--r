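# Harmonization: deterministic per-variable recoding of raw questionnaire
# variables into analysis-ready form. Fixed order of operations:
# conditional-question merging -> type classification -> "do not know"
# recoding -> category collapsing. Every transformation is appended to a
# per-variable audit that can replay the recoding from the raw columns.

harmonized_variable <- function(name, domain, var_type, values,
                                category_order = NULL, audit = list()) {
  structure(list(name = name, domain = domain, var_type = var_type,
                 values = values, category_order = category_order,
                 audit = audit),
            class = "harmonized_variable")
}

as_harmonized <- function(record, values) {
  harmonized_variable(record$name, record$domain, record$var_type, values,
                      category_order = record$levels)
}

#' Merge a conditional (skip-logic) question into its parent
#'
#' Conditional questions are asked only for subjects whose parent answer
#' equals the gate level, so in the raw table they carry structural
#' missingness. Merging produces one combined categorical variable whose
#' levels are the parent's non-gate levels plus the child's levels: a parent
#' answer of "Have you ever smoked?" = No maps to "No" (never smoked) while
#' gate-opened subjects take their child answer ("Do you still smoke?" =
#' Yes/No becomes current/past smoker).
#'
#' A missing parent, or a gate-opened subject with a missing child answer,
#' yields a missing merged value.
#'
#' @param parent,child [variable_record()]s with values attached via
#'   `values` fields or passed as `parent_values`/`child_values`.
#' @param parent_values,child_values Character vectors of raw observations.
#' @return A `harmonized_variable` named after the parent, with an audit
#'   entry describing the merge.
#' @export
merge_conditional <- function(parent, child, parent_values, child_values) {
  if (is.null(child$parent) || child$parent != parent$name) {
    stop_enwas(sprintf("'%s' does not declare '%s' as its parent",
                       child$name, parent$name), "enwas_dictionary_error")
  }
  gate <- child$parent_gate
  if (!is.null(parent$levels) && !gate %in% parent$levels) {
    stop_enwas(sprintf("gate '%s' absent from parent '%s' levels", gate,
                       parent$name), "enwas_dictionary_error")
  }
  non_gate <- setdiff(parent$levels %||% unique(stats::na.omit(parent_values)), gate)
  child_levels <- child$levels %||% unique(stats::na.omit(child_values))
  # rename child levels that collide with retained parent levels or echo
  # the gate label itself
  child_map <- stats::setNames(child_levels, child_levels)
  clash <- child_map %in% c(non_gate, gate)
  child_map[clash] <- paste(gate, child_map[clash], sep = ":")
  merged <- apply_merge(parent_values, child_values, gate, child_map)
  audit <- list(list(step = "merge_conditional", parent = parent$name,
                     child = child$name, gate = gate,
                     child_map = as.list(child_map),
                     running_role = "none"))
  harmonized_variable(parent$name, parent$domain, "unordered_categorical",
                      merged, category_order = c(non_gate, unname(child_map)),
                      audit = audit)
}

apply_merge <- function(parent_values, child_values, gate, child_map) {
  child_map <- unlist(child_map)
  out <- as.character(parent_values)
  opened <- !is.na(parent_values) & parent_values == gate
  out[opened] <- unname(child_map[as.character(child_values[opened])])
  out[is.na(parent_values)] <- NA_character_
  out
}

#' Recode "do not know" answers to missing
#'
#' Answers declared as no-information labels carry no usable signal and are
#' set to missing; the labels are removed from the category set.
#'
#' @param var A `harmonized_variable` or [variable_record()].
#' @param values Raw values when `var` is a record.
#' @param dont_know_labels Labels to blank; defaults to the record's own.
#' @return The variable with no-information answers set to `NA` and an audit
#'   entry appended.
#' @export
recode_dont_know <- function(var, values = NULL, dont_know_labels = NULL) {
  hv <- if (inherits(var, "harmonized_variable")) var else as_harmonized(var, values)
  labels <- dont_know_labels %||% var$dont_know_labels %||% character()
  if (length(labels) == 0L) return(hv)
  hit <- !is.na(hv$values) & hv$values %in% labels
  hv$values[hit] <- NA
  hv$category_order <- setdiff(hv$category_order, labels)
  hv$audit <- c(hv$audit, list(list(step = "recode_dont_know",
                                    labels = as.character(labels))))
  hv
}

#' Collapse sparse or badly shaped category sets
#'
#' Applies three deterministic rules in fixed order (a) then (b) then (c):
#' \describe{
#'   \item{(a) lopsided}{Ordered variables with 4+ levels whose terminal
#'     category on one side holds at least `lopsided_threshold` of nonmissing
#'     answers are recoded to 3 levels: that terminal, the adjacent level,
#'     and the pooled remainder (the "Never / Between never and frequent /
#'     Frequent" pattern).}
#'   \item{(b) centered}{Ordered variables with 5+ levels whose middle
#'     category is modal and holds at least `centered_threshold` are recoded
#'     to pooled-left / middle / pooled-right.}
#'   \item{(c) sparse}{Any category holding less than `sparse_threshold` of
#'     nonmissing answers is merged into its nearest neighbor (ordered; the
#'     adjacent level with the larger count, earlier level on ties) or into a
#'     pooled "other" level (unordered), repeating until no sparse category
#'     remains or only 2 levels are left.}
#' }
#'
#' @param var A `harmonized_variable` (categorical).
#' @param lopsided_threshold,centered_threshold,sparse_threshold Proportions
#'   of nonmissing responses parameterizing rules (a), (b) and (c).
#' @return The variable with collapsed values/levels and an audit entry
#'   holding the full label map.
#' @export
collapse_categories <- function(var, lopsided_threshold = 0.5,
                                centered_threshold = 0.4,
                                sparse_threshold = 0.05) {
  stopifnot(inherits(var, "harmonized_variable"))
  if (var$var_type == "continuous") return(var)
  lev <- var$category_order %||% sort(unique(stats::na.omit(var$values)))
  lev <- lev[lev %in% var$values]               # observed levels only
  if (length(lev) < 2L) return(var)             # constancy filter's problem
  map <- stats::setNames(lev, lev)              # raw level -> current label
  cur <- lev                                    # current labels in order
  counts <- function() {
    tab <- table(factor(unname(map[as.character(var$values)]), levels = cur))
    as.numeric(tab) / sum(tab)
  }
  pooled <- function(labels) paste(labels, collapse = "+")
  relabel <- function(from, to) {
    map[map %in% from] <<- to
    keep <- !duplicated(ifelse(cur %in% from, to, cur))
    cur <<- ifelse(cur %in% from, to, cur)[keep]
  }
  ordered <- var$var_type == "ordered_categorical"
  k <- length(cur)
  sh <- counts()
  # (a) lopsided
  if (ordered && k >= 4L && max(sh[1L], sh[k]) >= lopsided_threshold) {
    if (sh[1L] >= sh[k]) {
      relabel(cur[3:k], pooled(cur[3:k]))
    } else {
      relabel(cur[1:(k - 2L)], pooled(cur[1:(k - 2L)]))
    }
  }
  # (b) centered
  k <- length(cur); sh <- counts()
  if (ordered && k >= 5L) {
    mid <- k %/% 2L + 1L
    if (sh[mid] == max(sh) && sh[mid] >= centered_threshold) {
      left <- cur[1:(mid - 1L)]
      right <- cur[(mid + 1L):k]
      relabel(left, pooled(left))
      relabel(right, pooled(right))
    }
  }
  # (c) sparse
  repeat {
    k <- length(cur)
    if (k <= 2L) break
    sh <- counts()
    sparse <- which(sh < sparse_threshold)
    if (length(sparse) == 0L) break
    i <- sparse[1L]
    if (ordered) {
      nb <- if (i == 1L) 2L else if (i == k) k - 1L
      else if (sh[i + 1L] > sh[i - 1L]) i + 1L else i - 1L
      pair <- sort(c(i, nb))
      relabel(cur[pair], pooled(cur[pair]))
    } else {
      keep_labels <- setdiff(cur, cur[sparse])
      other <- if ("other" %in% keep_labels) ".other" else "other"
      if (identical(cur[sparse], other)) {
        # the pooled remainder itself is sparse; fold it into the smallest
        # retained category instead of spinning
        tgt <- keep_labels[which.min(sh[match(keep_labels, cur)])]
        relabel(c(cur[sparse], tgt), paste(tgt, other, sep = "+"))
      } else {
        relabel(cur[sparse], other)
      }
    }
  }
  if (any(map != names(map))) {
    var$values <- ifelse(is.na(var$values), NA_character_,
                         unname(map[as.character(var$values)]))
    var$category_order <- cur
    var$audit <- c(var$audit, list(list(step = "collapse_categories",
                                        map = as.list(map))))
  }
  var
}

#' Classify a variable as unordered, ordered, or continuous
#'
#' Returns the declared type label; when undeclared, infers one (numeric
#' values with more than 10 distinct observed values are continuous,
#' declared ordered levels make an ordered categorical, anything else is
#' unordered) and flags the inference.
#'
#' @param var A [variable_record()].
#' @param values Observed raw values.
#' @return List with `var_type` and `inferred` flag.
#' @export
classify_variable <- function(var, values) {
  if (!is.na(var$var_type %||% NA_character_)) {
    return(list(var_type = var$var_type, inferred = FALSE))
  }
  obs <- stats::na.omit(values)
  numeric_ok <- length(obs) > 0 && !anyNA(suppressWarnings(as.numeric(obs)))
  if (!numeric_ok && is.character(obs) &&
      any(!is.na(suppressWarnings(as.numeric(obs))))) {
    stop_enwas(sprintf("variable '%s': mixed numeric/text values without a declared type",
                       var$name), "enwas_classification_error")
  }
  type <- if (numeric_ok && length(unique(obs)) > 10L) {
    "continuous"
  } else if (!is.null(var$levels)) {
    "ordered_categorical"
  } else {
    "unordered_categorical"
  }
  list(var_type = type, inferred = TRUE)
}

#' Harmonize a whole cohort against its dictionary
#'
#' Runs the full per-variable recoding pipeline: conditional children are
#' merged into their parents (deepest chains first), types are classified,
#' "do not know" answers are blanked, and category sets are collapsed.
#'
#' @param data Raw cohort data frame.
#' @param dictionary An `enwas_dictionary` covering the exposure columns.
#' @param lopsided_threshold,centered_threshold,sparse_threshold Passed to
#'   [collapse_categories()].
#' @return List with the harmonized `data`, the updated `dictionary`, and a
#'   per-variable `audit` list replayable via [audit_replay()].
#' @export
harmonize_cohort <- function(data, dictionary, lopsided_threshold = 0.5,
                             centered_threshold = 0.4, sparse_threshold = 0.05) {
  recs <- dictionary
  vals <- list()
  audits <- list()
  for (nm in names(recs)) {
    if (!nm %in% names(data)) {
      stop_enwas(sprintf("dictionary variable '%s' missing from data", nm),
                 "enwas_dictionary_error")
    }
    vals[[nm]] <- data[[nm]]
    audits[[nm]] <- list()
  }
  # conditional merges, deepest chains first
  depth <- function(nm) {
    d <- 0L
    while (!is.null(recs[[nm]]$parent)) {
      d <- d + 1L
      nm <- recs[[nm]]$parent
    }
    d
  }
  children <- names(recs)[vapply(recs, function(r) !is.null(r$parent), logical(1))]
  children <- children[order(-vapply(children, depth, integer(1)))]
  for (ch in children) {
    pa <- recs[[ch]]$parent
    hv <- merge_conditional(recs[[pa]], recs[[ch]], vals[[pa]], vals[[ch]])
    step <- hv$audit[[1L]]
    step$running_role <- if (length(audits[[pa]])) "parent"
                         else if (length(audits[[ch]])) "child" else "none"
    dk <- union(recs[[pa]]$dont_know_labels, recs[[ch]]$dont_know_labels)
    recs[[pa]] <- variable_record(pa, recs[[pa]]$domain, hv$var_type,
                                  levels = hv$category_order,
                                  dont_know_labels = dk)
    vals[[pa]] <- hv$values
    audits[[pa]] <- c(audits[[pa]], audits[[ch]], list(step))
    recs[[ch]] <- NULL
    vals[[ch]] <- NULL
    audits[[ch]] <- NULL
  }
  out <- data[, !names(data) %in% setdiff(names(dictionary), names(recs)),
              drop = FALSE]
  for (nm in names(recs)) {
    r <- recs[[nm]]
    cls <- classify_variable(r, vals[[nm]])
    if (cls$inferred) {
      audits[[nm]] <- c(audits[[nm]],
                        list(list(step = "classify_variable",
                                  label = cls$var_type, inferred = TRUE)))
    }
    r$var_type <- cls$var_type
    hv <- harmonized_variable(nm, r$domain, r$var_type,
                              if (r$var_type == "continuous")
                                suppressWarnings(as.numeric(vals[[nm]]))
                              else as.character(vals[[nm]]),
                              category_order = r$levels)
    hv <- recode_dont_know(hv, dont_know_labels = r$dont_know_labels)
    hv <- collapse_categories(hv, lopsided_threshold, centered_threshold,
                              sparse_threshold)
    audits[[nm]] <- c(audits[[nm]], hv$audit)
    out[[nm]] <- hv$values
    recs[[nm]] <- variable_record(nm, r$domain, hv$var_type,
                                  levels = if (hv$var_type != "continuous")
                                    hv$category_order)
  }
  list(data = out, dictionary = enwas_dictionary(unname(recs)), audit = audits)
}

#' Replay a harmonization audit against raw columns
#'
#' Deterministically reconstructs a harmonized variable's values from the raw
#' cohort columns and its audit trail; used to verify that the audit fully
#' documents the recoding.
#'
#' @param audit One variable's audit (list of steps).
#' @param raw_data The raw cohort data frame.
#' @param name The harmonized variable's name (its raw source column when no
#'   merge step is present).
#' @return Recoded values.
#' @export
audit_replay <- function(audit, raw_data, name) {
  val <- NULL
  for (step in audit) {
    val <- switch(step$step,
      merge_conditional = {
        pv <- if (identical(step$running_role, "parent")) val
              else raw_data[[step$parent]]
        cv <- if (identical(step$running_role, "child")) val
              else raw_data[[step$child]]
        apply_merge(pv, cv, step$gate, step$child_map)
      },
      recode_dont_know = {
        v <- val %||% as.character(raw_data[[name]])
        v[!is.na(v) & v %in% unlist(step$labels)] <- NA
        v
      },
      collapse_categories = {
        v <- val %||% as.character(raw_data[[name]])
        m <- unlist(step$map)
        ifelse(is.na(v), NA_character_, unname(m[as.character(v)]))
      },
      classify_variable = {
        v <- val %||% raw_data[[name]]
        if (identical(step$label, "continuous"))
          suppressWarnings(as.numeric(v)) else as.character(v)
      },
      stop_enwas(sprintf("unknown audit step '%s'", step$step), "enwas_audit_error"))
  }
  if (is.null(val)) val <- raw_data[[name]]
  val
}

#' Write a harmonization audit as JSON lines
#'
#' @param audit The `audit` element of [harmonize_cohort()] output.
#' @param path Output file; one JSON record per transformation.
#' @export
write_audit <- function(audit, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(audit)) {
    for (step in audit[[nm]]) {
      writeLines(jsonlite::toJSON(c(list(variable = nm), step),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
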