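#' Color attached to an ordinal score
#'
#' Thematic and global presentation uses a quadri-chromatic code:
#' 0 = green, 1 = yellow, 2 = orange and 3 (or more, after vulnerability
#' penalties) = red.
#'
#' @param score Integer score(s), possibly above 3 after penalties.
#' @return Character vector of colors; `NA` score gives `NA`.
#' @export
score_color <- function(score) {
  ifelse(is.na(score), NA_character_,
         ifelse(score <= 0, "green",
                ifelse(score == 1, "yellow",
                       ifelse(score == 2, "orange", "red"))))
}

#' Apply occupant-vulnerability penalties to variable scores
#'
#' For each scored variable and each vulnerability present in the dwelling,
#' the matching rule fires when the pre-penalty score is at or above the
#' rule's trigger threshold, adding one point. Rules are evaluated against
#' the pre-penalty score only (a rule cannot re-trigger off another rule's
#' penalty), distinct vulnerabilities stack on the same variable, and
#' adjusted scores are not capped at 3: a variable rated 3 with a firing
#' rule becomes 4. Unscored variables stay unscored.
#'
#' @param a A validated `domiscore_assessment`.
#' @param matrix A `vulnerability_matrix`, or `NULL` for no penalties.
#' @param grid The `domiscore_grid` the assessment refers to.
#' @return Named integer vector over all grid variables (grid order):
#'   adjusted scores, `NA` where unscored.
#' @export
#' @examples
#' g <- load_grid(domiscore_grid_file("2020-11"))
#' m <- load_matrix(domiscore_matrix_file())
#' a <- assessment("2020-11", list(ventilation = 3),
#'                 vulnerabilities = "young_children_u4")
#' apply_vulnerability_penalties(a, m, g)[["ventilation"]]  # 4
apply_vulnerability_penalties <- function(a, matrix, grid) {
  validate_assessment(a, grid, check_version = FALSE)
  pre <- assessment_scores(a, grid)
  if (is.null(matrix) || !length(a$vulnerabilities)) return(pre)
  stopifnot(inherits(matrix, "vulnerability_matrix"))
  adj <- pre
  r <- matrix$rules
  r <- r[r$vulnerability %in% a$vulnerabilities & r$variable_id %in% names(pre), ,
         drop = FALSE]
  if (nrow(r)) {
    for (k in seq_len(nrow(r))) {
      id <- r$variable_id[k]
      if (!is.na(pre[[id]]) && pre[[id]] >= r$trigger_threshold[k]) {
        adj[[id]] <- adj[[id]] + r$penalty_points[k]
      }
    }
  }
  adj
}

#' Thematic scores by aspiration-level aggregation
#'
#' Each thematic category takes the highest (poorest) score obtained on at
#' least one of its scored variables; a category in which no variable was
#' scored is blank (white). The contributing variable is the first one in
#' grid order attaining the category maximum.
#'
#' @param scores Named integer vector of (possibly vulnerability-adjusted)
#'   variable scores, `NA` where unscored.
#' @param grid A `domiscore_grid`.
#' @return data.frame with one row per category in grid order: `category_id`,
#'   `label`, `score` (`NA` when blank), `color` (`NA` when blank), `blank`,
#'   `contributing_variable`.
#' @export
thematic_scores <- function(scores, grid) {
  stopifnot(inherits(grid, "domiscore_grid"))
  unknown <- setdiff(names(scores), grid_variable_ids(grid))
  if (length(unknown)) {
    stop("scores reference unknown variable id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(grid$categories, function(cc) {
    vids <- as.character(unlist(cc$variable_ids))
    s <- scores[vids]
    scored <- !is.na(s)
    if (!any(scored)) {
      data.frame(category_id = cc$id, label = cc$label, score = NA_integer_,
                 color = NA_character_, blank = TRUE,
                 contributing_variable = NA_character_, stringsAsFactors = FALSE)
    } else {
      mx <- max(s[scored])
      data.frame(category_id = cc$id, label = cc$label, score = as.integer(mx),
                 color = score_color(mx), blank = FALSE,
                 contributing_variable = vids[scored & s == mx][1L],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Missing-data penalty
#'
#' When one or more thematic categories are blank, a penalty equal to the
#' mean of the completed thematic scores (sum of completed scores divided by
#' the number of completed categories) is added to the global score, on the
#' assumption that absent information more likely hides a poor situation
#' than a good one. The penalty is kept as an exact integer rational.
#'
#' @param thematic data.frame from [thematic_scores()].
#' @param mode `"single_mean"` (default: the mean is added once, the literal
#'   reading) or `"mean_per_blank"` (the mean is added once per blank
#'   category, i.e. mean-imputation of the blanks).
#' @return List with `numerator`, `denominator` (unreduced integers),
#'   `value` (numeric), `n_blank`, `mode`. Zero when no category is blank.
#' @export
missing_penalty <- function(thematic, mode = c("single_mean", "mean_per_blank")) {
  mode <- match.arg(mode)
  n_blank <- sum(thematic$blank)
  n_completed <- sum(!thematic$blank)
  if (n_completed == 0L) {
    stop("unscorable: every thematic category is blank", call. = FALSE)
  }
  if (n_blank == 0L) {
    return(list(numerator = 0L, denominator = 1L, value = 0, n_blank = 0L, mode = mode))
  }
  raw_sum <- sum(thematic$score[!thematic$blank])
  num <- if (mode == "single_mean") raw_sum else raw_sum * n_blank
  list(numerator = as.integer(num), denominator = as.integer(n_completed),
       value = num / n_completed, n_blank = as.integer(n_blank), mode = mode)
}

# half-away-from-zero rounding of the exact rational raw_sum + num/den,
# done in integer arithmetic so .5 ties never touch floating point
round_global <- function(raw_sum, num, den) {
  total_num <- raw_sum * den + num   # value = total_num / den, nonnegative
  as.integer((2L * total_num + den) %/% (2L * den))
}

#' Class boundaries for a given number of themes
#'
#' The score range is segmented into four equivalence classes by standard
#' profiles: if half plus one of all themes reach a level k, the resulting
#' sum (floor(n/2)+1) * k belongs to class k's range. With 15 themes the
#' lower bounds are (7+1)*1 = 8 (yellow), (7+1)*2 = 16 (orange) and
#' (7+1)*3 = 24 (red); the red class is unbounded above because penalties
#' can push the global score past 3*n.
#'
#' @param n_themes Number of thematic categories (>= 1).
#' @return Object of class `domiscore_boundaries`: list with `n_themes` and
#'   `lower_bounds` (named integer vector: yellow, orange, red minima).
#' @export
#' @examples
#' class_boundaries(15)$lower_bounds  # 8 16 24
#' class_boundaries(16)$lower_bounds  # 9 18 27
class_boundaries <- function(n_themes) {
  n_themes <- as.integer(n_themes)
  if (is.na(n_themes) || n_themes < 1L) stop("n_themes must be >= 1", call. = FALSE)
  base <- n_themes %/% 2L + 1L
  structure(list(n_themes = n_themes,
                 lower_bounds = c(yellow = base, orange = 2L * base, red = 3L * base)),
            class = "domiscore_boundaries")
}

#' @export
print.domiscore_boundaries <- function(x, ...) {
  b <- x$lower_bounds
  mx <- 3L * x$n_themes
  cat("Domiscore equivalence classes for ", x$n_themes, " themes:\n", sep = "")
  cat(sprintf("  green  %d-%d\n", 0L, b[["yellow"]] - 1L))
  cat(sprintf("  yellow %d-%d\n", b[["yellow"]], b[["orange"]] - 1L))
  cat(sprintf("  orange %d-%d\n", b[["orange"]], b[["red"]] - 1L))
  cat(sprintf("  red    %d-%d (or more if penalties are applied)\n", b[["red"]], mx))
  invisible(x)
}

#' Equivalence class of a global score
#'
#' @param global_score Nonnegative integer global score.
#' @param n_themes Number of thematic categories in the grid.
#' @return `"green"`, `"yellow"`, `"orange"` or `"red"` (red is open-ended
#'   above).
#' @export
#' @examples
#' classify_score(7, 15)   # "green"
#' classify_score(24, 15)  # "red"
classify_score <- function(global_score, n_themes) {
  if (any(global_score < 0)) stop("global_score must be nonnegative", call. = FALSE)
  b <- class_boundaries(n_themes)$lower_bounds
  ifelse(global_score < b[["yellow"]], "green",
         ifelse(global_score < b[["orange"]], "yellow",
                ifelse(global_score < b[["red"]], "orange", "red")))
}

#' Detect risk situations that must be reported
#'
#' Every scored variable carrying an alert threshold whose (adjusted) score
#' reaches that threshold is flagged. Scoring always continues past alerts;
#' the engine flags, it does not transmit.
#'
#' @param scores Named integer vector of adjusted variable scores (`NA`
#'   where unscored).
#' @param grid A `domiscore_grid`.
#' @return data.frame with columns `variable_id`, `score`,
#'   `alert_threshold`, in grid order; zero rows when nothing fires.
#' @export
detect_alerts <- function(scores, grid) {
  av <- alert_variables(grid)
  if (!nrow(av)) {
    return(data.frame(variable_id = character(0), score = integer(0),
                      alert_threshold = integer(0), stringsAsFactors = FALSE))
  }
  s <- scores[av$variable_id]
  fire <- !is.na(s) & s >= av$alert_threshold
  out <- data.frame(variable_id = av$variable_id[fire],
                    score = as.integer(s[fire]),
                    alert_threshold = av$alert_threshold[fire],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compute the Domiscore of a dwelling assessment
#'
#' Orchestrates the full scoring pipeline: occupant-vulnerability penalties
#' on variable scores, aspiration-level thematic aggregation, missing-data
#' penalty, global score (sum of completed thematic scores plus penalty,
#' rounded half away from zero), traffic-light equivalence class for the
#' grid's theme count, risk alerts, and the variable completion rate.
#'
#' @param a A `domiscore_assessment`.
#' @param grid The `domiscore_grid` matching the assessment's version.
#' @param matrix Optional `vulnerability_matrix`; `NULL` disables occupant
#'   penalties.
#' @param penalty_mode Missing-data penalty mode, see [missing_penalty()].
#' @return Object of class `domiscore_result`; see Details.
#' @details The returned object holds `thematic` (per-category data.frame
#'   with scores, colors, blanks and contributing variables), `n_completed`,
#'   `raw_sum`, the penalty as an exact rational (`penalty_numerator` /
#'   `penalty_denominator`, also formatted in `penalty_fraction` and as the
#'   numeric `penalty`), `global_score`, `equivalence_class`, `alerts`,
#'   `completion_rate`, `adjusted_scores`, plus the grid version, theme
#'   count and penalty mode for provenance. An assessment in which every
#'   category is blank is an error: an unobservable dwelling has no
#'   Domiscore.
#' @export
#' @examples
#' g <- load_grid(domiscore_grid_file("2020-11"))
#' a <- assessment("2020-11",
#'                 stats::setNames(as.list(rep(0, 46)),
#'                                 vapply(g$variables, `[[`, "", "id")))
#' domiscore(a, g)
domiscore <- function(a, grid, matrix = NULL,
                      penalty_mode = c("single_mean", "mean_per_blank")) {
  penalty_mode <- match.arg(penalty_mode)
  stopifnot(inherits(grid, "domiscore_grid"))
  validate_assessment(a, grid)
  if (!is.null(matrix)) {
    viol <- validate_matrix(matrix, grid)
    if (length(viol)) {
      stop("vulnerability matrix inconsistent with grid: ", viol[1L], call. = FALSE)
    }
  }
  adjusted <- apply_vulnerability_penalties(a, matrix, grid)
  thematic <- thematic_scores(adjusted, grid)
  pen <- missing_penalty(thematic, penalty_mode)
  raw_sum <- as.integer(sum(thematic$score[!thematic$blank]))
  global <- round_global(raw_sum, pen$numerator, pen$denominator)
  n_themes <- length(grid$categories)
  structure(
    list(thematic = thematic,
         n_completed = as.integer(sum(!thematic$blank)),
         raw_sum = raw_sum,
         penalty_numerator = pen$numerator,
         penalty_denominator = pen$denominator,
         penalty = pen$value,
         penalty_fraction = paste0(pen$numerator, "/", pen$denominator),
         penalty_mode = penalty_mode,
         n_blank = as.integer(sum(thematic$blank)),
         global_score = global,
         equivalence_class = classify_score(global, n_themes),
         alerts = detect_alerts(adjusted, grid),
         completion_rate = completion_rate(a, grid),
         adjusted_scores = adjusted,
         grid_version = grid$version,
         n_themes = as.integer(n_themes)),
    class = "domiscore_result")
}

#' @export
print.domiscore_result <- function(x, ...) {
  cat("Domiscore (grid ", x$grid_version, ", ", x$n_themes, " themes)\n", sep = "")
  cat("  global score: ", x$global_score, "  class: ", x$equivalence_class, "\n", sep = "")
  if (x$n_blank > 0L) {
    cat("  raw sum ", x$raw_sum, " + missing-data penalty ", x$penalty_fraction,
        " (", format(round(x$penalty, 3)), "), ", x$n_blank, " blank categor",
        if (x$n_blank == 1L) "y" else "ies", "\n", sep = "")
  }
  cat("  completion rate: ", sprintf("%.0f%%", 100 * x$completion_rate), "\n", sep = "")
  prof <- ifelse(x$thematic$blank, "white", x$thematic$color)
  cat("  profile: ", paste(prof, collapse = " "), "\n", sep = "")
  if (nrow(x$alerts)) {
    cat("  ALERTS (report to authorities): ",
        paste0(x$alerts$variable_id, "=", x$alerts$score, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.domiscore_result <- function(object, ...) {
  print(object)
  cat("\nThematic detail:\n")
  print(object$thematic, row.names = FALSE)
  invisible(object)
}

#' @export
as.data.frame.domiscore_result <- function(x, ...) {
  data.frame(grid_version = x$grid_version,
             n_themes = x$n_themes,
             n_completed = x$n_completed,
             n_blank = x$n_blank,
             raw_sum = x$raw_sum,
             penalty_fraction = x$penalty_fraction,
             penalty = x$penalty,
             penalty_mode = x$penalty_mode,
             global_score = x$global_score,
             equivalence_class = x$equivalence_class,
             n_alerts = nrow(x$alerts),
             completion_rate = x$completion_rate,
             stringsAsFactors = FALSE)
}

#' Export a scoring result as a structured document
#'
#' The penalty is emitted both as the exact fraction (e.g. `"18/12"`) and as
#' a decimal.
#'
#' @param x A `domiscore_result`.
#' @param path Output path (JSON standard, YAML by extension).
#' @export
write_result <- function(x, path) {
  stopifnot(inherits(x, "domiscore_result"))
  doc <- unclass(x)
  doc$adjusted_scores <- as.list(doc$adjusted_scores[!is.na(doc$adjusted_scores)])
  write_structured_document(doc, path)
  invisible(path)
}
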