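#' Declare a dictionary entry for one cohort variable
#'
#' A variable record couples one raw cohort column with the metadata the
#' harmonization rules need: its measurement type, topical domain, category
#' order (for ordered categoricals), an optional conditional-question parent,
#' and the labels that mean "no information".
#'
#' @param name Column name in the cohort table.
#' @param domain Topical domain label (e.g., `"parental_health"`).
#' @param var_type One of `"unordered_categorical"`, `"ordered_categorical"`,
#'   `"continuous"`, or `NA` to request type inference at harmonization time.
#' @param levels Character vector of category labels; for ordered
#'   categoricals the vector order is the category order. Must be `NULL` for
#'   continuous variables.
#' @param parent Name of the conditional parent question, or `NULL`.
#' @param parent_gate The parent answer that triggers this question
#'   (required when `parent` is set).
#' @param dont_know_labels Character vector of labels to be recoded to
#'   missing (e.g., `"Do not know"`).
#' @return A `variable_record` list.
#' @export
variable_record <- function(name, domain, var_type = NA_character_,
                            levels = NULL, parent = NULL, parent_gate = NULL,
                            dont_know_labels = character()) {
  types <- c("unordered_categorical", "ordered_categorical", "continuous")
  if (!is.na(var_type) && !var_type %in% types) {
    stop_enwas(sprintf("unknown var_type '%s'", var_type), "enwas_dictionary_error")
  }
  if (identical(var_type, "continuous") && !is.null(levels)) {
    stop_enwas(sprintf("continuous variable '%s' must not declare levels", name),
               "enwas_dictionary_error")
  }
  if (!is.null(parent) && is.null(parent_gate)) {
    stop_enwas(sprintf("variable '%s' declares a parent but no parent_gate", name),
               "enwas_dictionary_error")
  }
  structure(list(name = as.character(name), domain = as.character(domain),
                 var_type = var_type, levels = levels,
                 parent = parent, parent_gate = parent_gate,
                 dont_know_labels = as.character(dont_know_labels)),
            class = "variable_record")
}

#' Assemble and validate a data dictionary
#'
#' Checks referential integrity of conditional-question links (parents exist,
#' gates are declared parent levels, no cycles) and wraps the records in an
#' `enwas_dictionary` keyed by variable name.
#'
#' @param records List of [variable_record()] entries.
#' @return An `enwas_dictionary` (named list of records).
#' @export
enwas_dictionary <- function(records) {
  nms <- vapply(records, function(r) r$name, character(1))
  if (anyDuplicated(nms)) {
    stop_enwas("duplicate variable names in dictionary", "enwas_dictionary_error")
  }
  names(records) <- nms
  for (r in records) {
    if (!is.null(r$parent)) {
      if (!r$parent %in% nms) {
        stop_enwas(sprintf("parent '%s' of '%s' is not in the dictionary",
                           r$parent, r$name), "enwas_dictionary_error")
      }
      plev <- records[[r$parent]]$levels
      if (!is.null(plev) && !r$parent_gate %in% plev) {
        stop_enwas(sprintf("gate '%s' is not a level of parent '%s'",
                           r$parent_gate, r$parent), "enwas_dictionary_error")
      }
    }
  }
  # cycle detection over parent links
  for (start in nms) {
    seen <- character()
    cur <- start
    while (!is.null(records[[cur]]$parent)) {
      if (cur %in% seen) {
        stop_enwas(sprintf("cyclic parent links involving '%s'", cur),
                   "enwas_dictionary_error")
      }
      seen <- c(seen, cur)
      cur <- records[[cur]]$parent
    }
  }
  structure(records, class = "enwas_dictionary")
}

#' Read a data dictionary from JSON or YAML
#'
#' One entry per variable with fields `name`, `domain`, `type`, `levels`,
#' `parent`, `parent_gate`, `dont_know_labels`.
#'
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return An `enwas_dictionary`.
#' @export
read_dictionary <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop_enwas(sprintf("unsupported dictionary format '.%s'", ext),
               "enwas_dictionary_error"))
  recs <- lapply(raw, function(e) {
    variable_record(
      name = e$name, domain = e$domain,
      var_type = e$type %||% NA_character_,
      levels = if (length(e$levels)) unlist(e$levels) else NULL,
      parent = e$parent, parent_gate = e$parent_gate,
      dont_know_labels = if (length(e$dont_know_labels)) unlist(e$dont_know_labels) else character())
  })
  enwas_dictionary(recs)
}

#' Write a data dictionary to JSON or YAML
#'
#' @param dictionary An `enwas_dictionary`.
#' @param path Output path; format chosen by extension.
#' @export
write_dictionary <- function(dictionary, path) {
  entries <- lapply(unname(dictionary), function(r) {
    e <- list(name = r$name, domain = r$domain, type = r$var_type)
    if (!is.null(r$levels)) e$levels <- r$levels
    if (!is.null(r$parent)) {
      e$parent <- r$parent
      e$parent_gate <- r$parent_gate
    }
    if (length(r$dont_know_labels)) e$dont_know_labels <- r$dont_know_labels
    e
  })
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(entries, path)
  }
  invisible(path)
}

#' Read a cohort table from CSV/TSV
#'
#' @param path File path; delimiter chosen by extension (`.csv` vs `.tsv`/`.txt`).
#' @param na Missing-value sentinels (default empty cell and `"NA"`).
#' @return A `data.frame`, one row per subject.
#' @export
read_cohort <- function(path, na = c("", "NA")) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, na.strings = na,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a cohort table to CSV/TSV
#'
#' @param data A data frame.
#' @param path Output path; delimiter chosen by extension.
#' @export
write_cohort <- function(data, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' @export
print.enwas_dictionary <- function(x, ...) {
  types <- table(vapply(x, function(r) r$var_type, character(1)), useNA = "ifany")
  cat(sprintf("<enwas_dictionary> %d variables, %d domains\n", length(x),
              length(unique(vapply(x, function(r) r$domain, character(1))))))
  print(types)
  invisible(x)
}
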