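# Descriptive tables from the instrument's test phase (28 dwelling visits)
# and public consultation (151 respondents of 1266 contacts), shipped as
# transcribed counts under inst/extdata.

#' Public-consultation participation summary
#'
#' Recomputes the participation descriptives from the shipped respondent
#' counts: per-category shares of the 151 respondents and the overall
#' participation rate against the 1266-contact mailing list. Percentages
#' are rounded to whole percent, as printed reports do.
#'
#' @param n_contacts Size of the mailing list (default 1266).
#' @return List with `table` (category, n, pct), `n_responses`,
#'   `n_contacts`, `participation_pct`.
#' @export
#' @examples
#' consultation_summary()$participation_pct  # 12
consultation_summary <- function(n_contacts = 1266L) {
  f <- system.file("extdata", "consultation-profiles.csv", package = "domiscore",
                   mustWork = TRUE)
  tab <- utils::read.csv(f, stringsAsFactors = FALSE)
  n <- sum(tab$n)
  tab$pct <- round(100 * tab$n / n)
  list(table = tab, n_responses = n, n_contacts = as.integer(n_contacts),
       participation_pct = round(100 * n / n_contacts))
}

#' Test-phase visit profile summary
#'
#' Per-dimension shares (whole percent) of the 28 test visits: setting
#' (urban/rural), metropolitan vs overseas, collective vs individual
#' housing, and tenure.
#'
#' @return data.frame with `dimension`, `level`, `n`, `pct`.
#' @export
#' @examples
#' v <- visit_profile_summary()
#' v$pct[v$level == "urban"]  # 71
visit_profile_summary <- function() {
  f <- system.file("extdata", "test-phase-visits.csv", package = "domiscore",
                   mustWork = TRUE)
  tab <- utils::read.csv(f, stringsAsFactors = FALSE)
  totals <- stats::ave(tab$n, tab$dimension, FUN = sum)
  tab$pct <- round(100 * tab$n / totals)
  tab
}
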