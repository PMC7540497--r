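#' @importFrom rlang .data
NULL

# Presentation layer: Manhattan plots with the three threshold lines,
# a correlation heatmap over the exposure block structure, the nonresponse
# comparison, and the per-configuration significance-count table. Every
# artifact is a pure function of a results table (or cohort table), so it
# regenerates identically from saved results.

#' Manhattan plot of scan results
#'
#' One point per tested variable, grouped and colored by domain in
#' dictionary order. By default the y-axis is the -log10 FDR-adjusted joint
#' p; the red line at -log10(alpha) then separates FDR-significant
#' variables exactly. The green (uncorrected) and purple (Bonferroni) lines
#' are mapped onto the adjusted axis through the realized raw-to-adjusted
#' step function. With `adjusted = FALSE` the axis is the raw joint p and
#' the lines sit at their textbook positions: green at -log10(alpha),
#' purple at -log10(alpha/m), red at the realized BH step-up cutoff.
#'
#' @param results Scan results (the `results` element of an `enwas_scan`),
#'   or a results TSV re-read from disk.
#' @param stage Which stage to plot (default `"discovery"`).
#' @param adjusted Plot FDR-adjusted p (default) or raw p.
#' @param alpha Threshold level for all three lines.
#' @param domain_order Optional domain ordering (defaults to order of
#'   appearance).
#' @param out_file Optional path (png/pdf) to write.
#' @return The ggplot object (invisibly if written to file).
#' @export
manhattan_plot <- function(results, stage = "discovery", adjusted = TRUE,
                           alpha = 0.05, domain_order = NULL,
                           out_file = NULL) {
  res <- results[results$stage == stage & !duplicated(results$variable), ,
                 drop = FALSE]
  if (nrow(res) == 0L) stop_enwas("no results to plot", "enwas_plot_error")
  if (any(is.na(res$domain))) {
    stop_enwas("unknown (missing) domain labels in results", "enwas_plot_error")
  }
  domain_order <- domain_order %||% unique(res$domain)
  if (!all(res$domain %in% domain_order)) {
    stop_enwas("unknown domain label in results", "enwas_plot_error")
  }
  res$domain <- factor(res$domain, levels = domain_order)
  res <- res[order(res$domain), , drop = FALSE]
  res$pos <- seq_len(nrow(res))
  m <- nrow(res)
  floor_p <- .Machine$double.xmin
  if (adjusted) {
    res$logp <- -log10(pmax(res$p_fdr, floor_p))
    # map a raw threshold onto the adjusted axis: the adjusted value at the
    # largest raw p not exceeding the threshold
    map_thr <- function(thr) {
      below <- res$p_joint <= thr
      if (!any(below)) return(max(res$p_fdr))
      min(res$p_fdr[res$p_joint == max(res$p_joint[below])])
    }
    lines <- data.frame(
      threshold = c("uncorrected 0.05", "FDR 0.05", "Bonferroni 0.05"),
      y = -log10(pmax(c(map_thr(alpha), alpha, map_thr(alpha / m)), floor_p)))
  } else {
    res$logp <- -log10(pmax(res$p_joint, floor_p))
    ord <- sort(res$p_joint)
    pass <- ord <= seq_along(ord) * alpha / m
    bh_cut <- if (any(pass)) max(which(pass)) * alpha / m else alpha / m
    lines <- data.frame(
      threshold = c("uncorrected 0.05", "FDR 0.05", "Bonferroni 0.05"),
      y = -log10(c(alpha, bh_cut, alpha / m)))
  }
  lines$threshold <- factor(lines$threshold, levels = lines$threshold)
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$pos, y = .data$logp,
                                         color = .data$domain)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = lines,
                        ggplot2::aes(yintercept = .data$y,
                                     linetype = .data$threshold),
                        color = c("darkgreen", "red", "purple")) +
    ggplot2::labs(x = "variable (grouped by domain)",
                  y = if (adjusted) expression(-log[10]~"FDR-adjusted p")
                      else expression(-log[10]~"p"),
                  color = "domain", linetype = "threshold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(out_file)) {
    ggplot2::ggsave(out_file, p, width = 10, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Correlation heatmap of the exposure block structure
#'
#' Pairwise-complete Pearson correlations over numerically coded exposures
#' (continuous as-is, ordered as level scores, unordered as category codes),
#' ordered by domain, rendered with a diverging palette (red positive, blue
#' negative).
#'
#' @param data Cohort data frame.
#' @param dictionary `enwas_dictionary` naming the exposures; when `NULL`
#'   all numeric columns are used.
#' @param out_file Optional path to write.
#' @return List with the ggplot `plot` and the correlation matrix `cormat`.
#' @export
covariance_heatmap <- function(data, dictionary = NULL, out_file = NULL) {
  if (!is.null(dictionary)) {
    vars <- intersect(names(dictionary), names(data))
    doms <- vapply(dictionary[vars], function(r) r$domain, character(1))
    vars <- vars[order(match(doms, unique(doms)))]
    num <- sapply(vars, function(v) {
      r <- dictionary[[v]]
      if (r$var_type == "continuous") as.numeric(data[[v]])
      else as.numeric(match(data[[v]], r$levels %||%
                              sort(unique(stats::na.omit(data[[v]])))))
    })
  } else {
    keep <- vapply(data, is.numeric, logical(1))
    num <- as.matrix(data[, keep, drop = FALSE])
  }
  if (ncol(num) < 2L) stop_enwas("need at least 2 variables", "enwas_plot_error")
  cormat <- stats::cor(num, use = "pairwise.complete.obs")
  df <- expand.grid(v1 = factor(colnames(cormat), levels = colnames(cormat)),
                    v2 = factor(colnames(cormat), levels = colnames(cormat)))
  df$r <- as.vector(cormat)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$v1, y = .data$v2,
                                        fill = .data$r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
  if (!is.null(out_file)) ggplot2::ggsave(out_file, p, width = 7, height = 6,
                                          dpi = 150)
  list(plot = p, cormat = cormat)
}

#' Compare included and excluded subjects
#'
#' Per comparison variable: group means (continuous; Welch t-test) or group
#' proportions of the overall modal level (categorical; chi-square test),
#' the difference, and a two-sided p.
#'
#' @param included,excluded Data frames for the two groups.
#' @param compare_on Shared column names to compare.
#' @return Data frame, one row per comparison variable.
#' @export
nonresponse_comparison <- function(included, excluded, compare_on) {
  if (nrow(included) == 0L || nrow(excluded) == 0L) {
    stop_enwas("both groups must be nonempty", "enwas_report_error")
  }
  miss <- setdiff(compare_on, intersect(names(included), names(excluded)))
  if (length(miss)) {
    stop_enwas(sprintf("columns absent from both tables: %s",
                       paste(miss, collapse = ", ")), "enwas_report_error")
  }
  rows <- lapply(compare_on, function(v) {
    a <- included[[v]]
    b <- excluded[[v]]
    if (is.numeric(a)) {
      pv <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      data.frame(variable = v, type = "continuous",
                 mean_included = mean(a, na.rm = TRUE),
                 mean_excluded = mean(b, na.rm = TRUE),
                 difference = mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE),
                 p_value = pv, stringsAsFactors = FALSE)
    } else {
      lev <- modal_level(c(as.character(a), as.character(b)))
      tab <- rbind(table(factor(a, levels = unique(c(a, b)))),
                   table(factor(b, levels = unique(c(a, b)))))
      pv <- tryCatch(stats::chisq.test(tab)$p.value, error = function(e) NA_real_)
      pa <- mean(a == lev, na.rm = TRUE)
      pb <- mean(b == lev, na.rm = TRUE)
      data.frame(variable = v, type = "categorical",
                 mean_included = pa, mean_excluded = pb,
                 difference = pa - pb, p_value = pv, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Significance-count table across analysis configurations
#'
#' One row per configuration: variables tested, nominally significant
#' (p < alpha), and FDR-significant in the discovery stage, then the same
#' for the test stage (whose total equals the discovery FDR count by
#' construction of the two-stage design).
#'
#' @param reports Named list of `enwas_report`s (from `enwas_scan$report`).
#' @return Data frame of counts.
#' @export
counts_table <- function(reports) {
  rows <- lapply(names(reports), function(nm) {
    st <- reports[[nm]]$stages
    get <- function(stage, col) if (stage %in% rownames(st)) st[stage, col] else 0L
    first <- if ("combined" %in% rownames(st)) "combined" else "discovery"
    data.frame(analysis = nm,
               discovery_total = get(first, "total"),
               discovery_p05 = get(first, "p05"),
               discovery_fdr = get(first, "fdr"),
               test_total = get("test", "total"),
               test_p05 = get("test", "p05"),
               test_fdr = get("test", "fdr"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
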