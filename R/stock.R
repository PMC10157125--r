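#' Completion rate of an assessment
#'
#' Fraction of the grid's variables that received a score (unscored
#' variables, whatever the reason, count against completion).
#'
#' @param a A `domiscore_assessment`.
#' @param grid A `domiscore_grid`.
#' @return A fraction in `[0, 1]`.
#' @export
completion_rate <- function(a, grid) {
  validate_assessment(a, grid, check_version = FALSE)
  s <- assessment_scores(a, grid)
  sum(!is.na(s)) / length(s)
}

#' Summarize a scored housing stock at the territory level
#'
#' Aggregates per-dwelling scoring results into the descriptive picture a
#' community would use: equivalence-class counts, global-score statistics,
#' completion-rate statistics, the per-theme color-frequency table (the
#' territory "profile"), and the total alert count. Standard deviations use
#' the sample (n-1) convention and are `NA` for a single dwelling.
#'
#' @param results List of `domiscore_result` objects (all from the same
#'   grid version).
#' @return Object of class `stock_summary`.
#' @export
summarize_stock <- function(results) {
  if (!length(results)) stop("no results to summarize", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "domiscore_result")))
  versions <- unique(vapply(results, `[[`, "", "grid_version"))
  if (length(versions) > 1L) {
    stop("mixed grid versions in stock: ", paste(versions, collapse = ", "),
         call. = FALSE)
  }
  n <- length(results)
  gs <- vapply(results, `[[`, 0L, "global_score")
  cr <- vapply(results, `[[`, 0, "completion_rate")
  cls <- factor(vapply(results, `[[`, "", "equivalence_class"), levels = CLASS_LEVELS)
  cats <- results[[1L]]$thematic$category_id
  color_levels <- c(CLASS_LEVELS, "blank")
  freq <- t(vapply(seq_along(cats), function(j) {
    col <- vapply(results, function(r) {
      if (r$thematic$blank[j]) "blank" else r$thematic$color[j]
    }, "")
    table(factor(col, levels = color_levels))
  }, stats::setNames(integer(5), color_levels)))
  rownames(freq) <- cats
  structure(
    list(n_dwellings = n,
         grid_version = versions,
         penalty_mode = unique(vapply(results, `[[`, "", "penalty_mode")),
         class_counts = stats::setNames(as.integer(table(cls)), CLASS_LEVELS),
         global_score_stats = c(mean = mean(gs),
                                sd = if (n > 1L) stats::sd(gs) else NA_real_,
                                min = min(gs), max = max(gs)),
         completion_stats = c(mean = mean(cr),
                              sd = if (n > 1L) stats::sd(cr) else NA_real_),
         theme_color_frequencies = freq,
         alert_count = sum(vapply(results, function(r) nrow(r$alerts), 0L)),
         sd_convention = "sample (n-1)"),
    class = "stock_summary")
}

#' @export
print.stock_summary <- function(x, ...) {
  cat("Housing-stock summary: ", x$n_dwellings, " dwellings (grid ",
      x$grid_version, ", penalty mode ", x$penalty_mode, ")\n", sep = "")
  cc <- x$class_counts
  cat("  classes: ", paste(paste0(names(cc), "=", cc), collapse = ", "), "\n", sep = "")
  g <- x$global_score_stats
  cat(sprintf("  global score: mean %.2f (SD %s), range %d-%d\n",
              g[["mean"]], if (is.na(g[["sd"]])) "NA" else sprintf("%.2f", g[["sd"]]),
              as.integer(g[["min"]]), as.integer(g[["max"]])))
  cmp <- x$completion_stats
  cat(sprintf("  completion rate: mean %.1f%% (SD %s)\n", 100 * cmp[["mean"]],
              if (is.na(cmp[["sd"]])) "NA" else sprintf("%.1f%%", 100 * cmp[["sd"]])))
  cat("  alerts flagged: ", x$alert_count, "\n", sep = "")
  cat("  theme color frequencies:\n")
  print(x$theme_color_frequencies)
  invisible(x)
}

#' Compare two assessments of the same dwelling
#'
#' Repeat visits by different assessors support a simple reproducibility
#' check: the fraction of commonly scored variables rated identically, plus
#' signed per-category and global score differences (first minus second).
#' No chance-corrected coefficient is computed.
#'
#' @param a,b `domiscore_assessment` objects sharing a grid version.
#' @param grid The matching `domiscore_grid`.
#' @param matrix Optional `vulnerability_matrix` used when scoring each
#'   assessment.
#' @return Object of class `agreement_report`: `n_compared_variables`,
#'   `exact_agreement` (`NA` when no variable is scored in both),
#'   `per_category_score_delta`, `global_score_delta`.
#' @export
compare_assessments <- function(a, b, grid, matrix = NULL) {
  if (!identical(a$grid_version, b$grid_version)) {
    stop("assessments use different grid versions", call. = FALSE)
  }
  sa <- assessment_scores(a, grid)
  sb <- assessment_scores(b, grid)
  both <- !is.na(sa) & !is.na(sb)
  ra <- domiscore(a, grid, matrix)
  rb <- domiscore(b, grid, matrix)
  delta <- stats::setNames(
    ifelse(ra$thematic$blank | rb$thematic$blank, NA_integer_,
           ra$thematic$score - rb$thematic$score),
    ra$thematic$category_id)
  structure(
    list(n_compared_variables = as.integer(sum(both)),
         exact_agreement = if (any(both)) sum(sa[both] == sb[both]) / sum(both) else NA_real_,
         per_category_score_delta = delta,
         global_score_delta = ra$global_score - rb$global_score),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Repeat-visit agreement: ", x$n_compared_variables,
      " variables scored in both\n", sep = "")
  if (is.na(x$exact_agreement)) {
    cat("  exact agreement: undefined (no commonly scored variable)\n")
  } else {
    cat(sprintf("  exact agreement: %.1f%%\n", 100 * x$exact_agreement))
  }
  cat("  global score delta (a - b): ", x$global_score_delta, "\n", sep = "")
  invisible(x)
}

## ------------------------------------------------------------------
## territory report rendering

#' Render a territory report
#'
#' Writes the stock summary as plain text or as a static single-file HTML
#' page with the per-theme color-frequency table banded in the instrument's
#' traffic-light colors.
#'
#' @param summary A `stock_summary`.
#' @param path Output file path.
#' @param format `"text"` or `"html"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(summary, path, format = c("text", "html")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "stock_summary"))
  if (format == "text") {
    txt <- utils::capture.output(print(summary))
    writeLines(txt, path)
    return(invisible(path))
  }
  band <- c(green = "#2e7d32", yellow = "#f9a825", orange = "#ef6c00",
            red = "#c62828", blank = "#9e9e9e")
  freq <- summary$theme_color_frequencies
  head_cells <- paste0("<th style='background:", band[colnames(freq)],
                       ";color:white;padding:4px 8px'>", colnames(freq), "</th>",
                       collapse = "")
  rows <- vapply(rownames(freq), function(rn) {
    paste0("<tr><td style='padding:4px 8px'>", rn, "</td>",
           paste0("<td style='text-align:center'>", freq[rn, ], "</td>", collapse = ""),
           "</tr>")
  }, "")
  g <- summary$global_score_stats
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Territory housing profile</title></head><body>",
    "<h1>Territory housing profile</h1>",
    sprintf("<p>%d dwellings, grid %s, penalty mode %s.</p>",
            summary$n_dwellings, summary$grid_version, summary$penalty_mode),
    sprintf("<p>Global score: mean %.2f (SD %s), range %d&ndash;%d. Alerts: %d.</p>",
            g[["mean"]], if (is.na(g[["sd"]])) "NA" else sprintf("%.2f", g[["sd"]]),
            as.integer(g[["min"]]), as.integer(g[["max"]]), summary$alert_count),
    "<p>Equivalence classes: ",
    paste(sprintf("<span style='background:%s;color:white;padding:2px 6px'>%s %d</span>",
                  band[names(summary$class_counts)], names(summary$class_counts),
                  summary$class_counts), collapse = " "),
    "</p>",
    "<table border='0' cellspacing='1' style='border-collapse:collapse'>",
    paste0("<tr><th>theme</th>", head_cells, "</tr>"),
    rows,
    "</table></body></html>")
  writeLines(html, path)
  invisible(path)
}
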