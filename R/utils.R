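#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_enwas <- function(msg, class) {
  stop(structure(class = c(class, "enwas_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Share of the modal value among nonmissing entries; NA if all missing.
modal_share <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  max(table(x)) / length(x)
}

# Drop covariate columns that are constant (e.g., ethnicity in a
# Dutch-only subset) so model matrices stay full rank.
drop_constant_cols <- function(df) {
  keep <- vapply(df, function(col) length(unique(stats::na.omit(col))) > 1L,
                 logical(1))
  df[, keep, drop = FALSE]
}

modal_level <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1L]
}
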