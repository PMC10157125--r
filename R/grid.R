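SOURCE_TAGS <- c("in_situ", "mandatory_diagnostic", "open_data", "occupant_report")
VULNERABILITIES <- c("young_children_u4", "elderly_o70", "physical_disability",
                     "visual_disability", "hearing_disability")
MISSING_REASONS <- c("data_unavailable", "site_inaccessible", "diagnosis_unavailable",
                     "description_unclear", "other")
CLASS_LEVELS <- c("green", "yellow", "orange", "red")

#' Load and validate a Domiscore grid definition
#'
#' Reads a versioned grid document (JSON, or YAML with the same schema) and
#' validates it: unique variable and category identifiers, every variable
#' attached to exactly one existing category, level descriptions covering
#' exactly the four ordinal levels 0--3, information sources drawn from the
#' four-source taxonomy (in-situ observation, mandatory diagnostics, open
#' data, occupant reports), and alert thresholds, when present, in 1--3.
#'
#' @param source Path to a grid document (`.json`, `.yaml`/`.yml`), or an
#'   already-parsed list with the same structure.
#' @return A validated object of class `domiscore_grid`: a list with
#'   `version`, `schema_version`, `categories` (ordered list of
#'   `id`/`label`/`variable_ids`) and `variables` (ordered list of variable
#'   definitions, each with `id`, `label`, `category_id`, `position`,
#'   `sources`, `level_descriptions`, optional `alert_threshold`, `notes`).
#' @seealso [domiscore_grid_file()] for the packaged reconstructed fixtures,
#'   [alert_variables()], [load_matrix()].
#' @export
#' @examples
#' g <- load_grid(domiscore_grid_file("2020-11"))
#' g
load_grid <- function(source) {
  doc <- read_structured_document(source)
  validate_grid(doc)
}

#' @rdname load_grid
#' @param grid A parsed grid document (list).
#' @export
validate_grid <- function(grid) {
  if (!is.list(grid)) stop("grid document must be a list", call. = FALSE)
  for (f in c("version", "categories", "variables")) {
    if (is.null(grid[[f]])) stop("grid document lacks required field '", f, "'", call. = FALSE)
  }
  cats <- grid$categories
  vars <- grid$variables
  if (length(cats) < 1L) stop("grid must declare at least one category", call. = FALSE)
  cat_ids <- vapply(cats, function(x) as.character(x$id %||% stop("category without id", call. = FALSE)), "")
  if (anyDuplicated(cat_ids)) {
    stop("duplicate category id(s): ", paste(unique(cat_ids[duplicated(cat_ids)]), collapse = ", "),
         call. = FALSE)
  }
  var_ids <- vapply(vars, function(x) as.character(x$id %||% stop("variable without id", call. = FALSE)), "")
  if (anyDuplicated(var_ids)) {
    stop("duplicate variable id(s): ", paste(unique(var_ids[duplicated(var_ids)]), collapse = ", "),
         call. = FALSE)
  }
  # category membership lists: non-empty, referencing declared variables, a partition
  listed <- character(0)
  for (k in seq_along(cats)) {
    cats[[k]]$variable_ids <- as.character(unlist(cats[[k]]$variable_ids))
    cc <- cats[[k]]
    vids <- cc$variable_ids
    if (length(vids) < 1L) stop("category '", cc$id, "' declares no variables", call. = FALSE)
    unknown <- setdiff(vids, var_ids)
    if (length(unknown)) {
      stop("category '", cc$id, "' references unknown variable(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    listed <- c(listed, vids)
  }
  if (anyDuplicated(listed)) {
    stop("variable(s) assigned to more than one category: ",
         paste(unique(listed[duplicated(listed)]), collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(var_ids, listed)
  if (length(orphan)) {
    stop("variable(s) not assigned to any category: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    if (is.null(v$category_id) || !(v$category_id %in% cat_ids)) {
      stop("variable '", v$id, "' references unknown category '", v$category_id, "'",
           call. = FALSE)
    }
    if (!(v$id %in% cats[[match(v$category_id, cat_ids)]]$variable_ids)) {
      stop("variable '", v$id, "' not listed by its category '", v$category_id, "'",
           call. = FALSE)
    }
    lev <- unlist(v$level_descriptions)
    if (!setequal(names(lev), as.character(0:3)) || length(lev) != 4L) {
      stop("variable '", v$id, "' level descriptions must cover exactly levels 0-3",
           call. = FALSE)
    }
    src <- as.character(unlist(v$sources))
    if (length(src) < 1L || !all(src %in% SOURCE_TAGS)) {
      stop("variable '", v$id, "' sources must be a non-empty subset of: ",
           paste(SOURCE_TAGS, collapse = ", "), call. = FALSE)
    }
    at <- v$alert_threshold
    if (!is.null(at)) {
      at <- as.integer(at)
      if (is.na(at) || !(at %in% 1:3)) {
        stop("variable '", v$id, "' alert_threshold must be in {1,2,3}", call. = FALSE)
      }
    }
    # canonical in-memory form, independent of the source encoding
    vars[[i]]$level_descriptions <- as.list(lev[as.character(0:3)])
    vars[[i]]$sources <- src
    vars[[i]]$alert_threshold <- at
    vars[[i]]$position <- i
    vars[[i]]$notes <- as.character(v$notes %||% "")
  }
  grid$categories <- cats
  grid$variables <- vars
  structure(grid, class = "domiscore_grid")
}

#' Path to a packaged grid or matrix fixture
#'
#' The packaged fixtures are documented synthetic reconstructions of the two
#' instrument versions: `"2020-01"` (pre-testing, 47 variables in 15
#' categories) and `"2020-11"` (post-testing, 46 variables in 16 categories,
#' 9 alert variables). Their variable wording is placeholder text written
#' for this package, not the regulatory instrument.
#'
#' @param version `"2020-01"` or `"2020-11"`.
#' @return File path inside the installed package.
#' @export
domiscore_grid_file <- function(version = c("2020-11", "2020-01")) {
  version <- match.arg(version)
  system.file("extdata", paste0("grid-", version, "-reconstructed.json"),
              package = "domiscore", mustWork = TRUE)
}

#' @rdname domiscore_grid_file
#' @export
domiscore_matrix_file <- function() {
  system.file("extdata", "vulnerability-matrix-2020-11-reconstructed.json",
              package = "domiscore", mustWork = TRUE)
}

grid_variable_ids <- function(grid) {
  vapply(grid$variables, `[[`, "", "id")
}

grid_category_ids <- function(grid) {
  vapply(grid$categories, `[[`, "", "id")
}

grid_variable <- function(grid, id) {
  grid$variables[[match(id, grid_variable_ids(grid))]]
}

#' Variables whose score must be reported to the authorities
#'
#' Some variables flag risk situations: when rated at or above their alert
#' threshold the assessor must report the dwelling to the competent
#' authorities. Returns those variables, in grid order.
#'
#' @param grid A `domiscore_grid`.
#' @return A data.frame with columns `variable_id` and `alert_threshold`.
#' @export
#' @examples
#' alert_variables(load_grid(domiscore_grid_file("2020-11")))
alert_variables <- function(grid) {
  stopifnot(inherits(grid, "domiscore_grid"))
  keep <- !vapply(grid$variables, function(v) is.null(v$alert_threshold), logical(1))
  data.frame(
    variable_id = vapply(grid$variables[keep], `[[`, "", "id"),
    alert_threshold = vapply(grid$variables[keep], function(v) as.integer(v$alert_threshold), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Serialize a grid back to a document
#'
#' Writes the grid as JSON (or YAML, by file extension); reloading the file
#' with [load_grid()] round-trips to an equal grid.
#'
#' @param grid A `domiscore_grid`.
#' @param path Output file path (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "domiscore_grid"))
  write_structured_document(unclass(grid), path)
  invisible(path)
}

#' @export
print.domiscore_grid <- function(x, ...) {
  nv <- length(x$variables)
  nc <- length(x$categories)
  na <- nrow(alert_variables(x))
  cat("Domiscore grid version ", x$version, "\n", sep = "")
  cat("  ", nv, " variables in ", nc, " thematic categories; ",
      na, " alert variable", if (na == 1L) "" else "s", "\n", sep = "")
  sizes <- vapply(x$categories, function(cc) length(unlist(cc$variable_ids)), 0L)
  labs <- vapply(x$categories, `[[`, "", "label")
  cat(paste0("  - ", labs, " (", sizes, ")"), sep = "\n")
  invisible(x)
}

## ------------------------------------------------------------------
## vulnerability matrix

#' Load a vulnerability-penalty matrix
#'
#' The matrix lists rules `(vulnerability, variable, trigger threshold)`;
#' when an occupant with that vulnerability is present and the variable's
#' pre-penalty score reaches the trigger threshold, one penalty point is
#' added to the variable. The five recognized vulnerabilities are young
#' children (< 4 years), elderly people (> 70 years), and physical, visual
#' and hearing disability.
#'
#' @param source Path to a matrix document (JSON/YAML) or a parsed list.
#' @return Object of class `vulnerability_matrix`: list with `grid_version`
#'   and `rules` (a data.frame with columns `vulnerability`, `variable_id`,
#'   `trigger_threshold`, `penalty_points`, `placeholder`).
#' @export
load_matrix <- function(source) {
  doc <- read_structured_document(source)
  if (is.null(doc$rules)) stop("matrix document lacks 'rules'", call. = FALSE)
  rules <- do.call(rbind, lapply(doc$rules, function(r) {
    data.frame(
      vulnerability = as.character(r$vulnerability),
      variable_id = as.character(r$variable_id),
      trigger_threshold = as.integer(r$trigger_threshold),
      penalty_points = as.integer(r$penalty_points %||% 1L),
      placeholder = isTRUE(r$placeholder),
      stringsAsFactors = FALSE
    )
  }))
  structure(list(grid_version = doc$grid_version, rules = rules,
                 note = doc$note %||% NULL),
            class = "vulnerability_matrix")
}

#' Check a vulnerability matrix against a grid
#'
#' Violations are reported, not raised: unknown vulnerability kinds,
#' rules targeting variables absent from the grid, trigger thresholds
#' outside 1--3, penalty points other than 1, and duplicated
#' (vulnerability, variable) pairs.
#'
#' @param matrix A `vulnerability_matrix`.
#' @param grid A `domiscore_grid`.
#' @return Character vector of violation messages; empty when consistent.
#' @export
validate_matrix <- function(matrix, grid) {
  stopifnot(inherits(matrix, "vulnerability_matrix"), inherits(grid, "domiscore_grid"))
  r <- matrix$rules
  out <- character(0)
  bad <- !(r$vulnerability %in% VULNERABILITIES)
  if (any(bad)) {
    out <- c(out, paste0("unknown vulnerability '", r$vulnerability[bad], "'"))
  }
  known <- grid_variable_ids(grid)
  bad <- !(r$variable_id %in% known)
  if (any(bad)) {
    out <- c(out, paste0("rule targets unknown variable '", r$variable_id[bad], "'"))
  }
  bad <- is.na(r$trigger_threshold) | !(r$trigger_threshold %in% 1:3)
  if (any(bad)) {
    out <- c(out, paste0("rule for '", r$variable_id[bad],
                         "' has trigger_threshold outside {1,2,3}"))
  }
  bad <- r$penalty_points != 1L
  if (any(bad)) {
    out <- c(out, paste0("rule for '", r$variable_id[bad], "' has penalty_points != 1"))
  }
  key <- paste(r$vulnerability, r$variable_id)
  if (anyDuplicated(key)) {
    out <- c(out, paste0("duplicated rule: ", unique(key[duplicated(key)])))
  }
  if (!is.null(matrix$grid_version) && !identical(matrix$grid_version, grid$version)) {
    out <- c(out, paste0("matrix targets grid version '", matrix$grid_version,
                         "' but grid is '", grid$version, "'"))
  }
  out
}

#' @export
print.vulnerability_matrix <- function(x, ...) {
  cat("Vulnerability-penalty matrix for grid ", x$grid_version %||% "(unspecified)",
      ": ", nrow(x$rules), " rules on ", length(unique(x$rules$variable_id)),
      " variables\n", sep = "")
  print(x$rules[, c("vulnerability", "variable_id", "trigger_threshold")], row.names = FALSE)
  invisible(x)
}

## ------------------------------------------------------------------
## shared structured-document I/O (JSON standard, YAML alternate)

read_structured_document <- function(source) {
  if (is.list(source)) return(source)
  if (!is.character(source) || length(source) != 1L) {
    stop("source must be a file path or a parsed list", call. = FALSE)
  }
  if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(source)
  } else {
    jsonlite::fromJSON(source, simplifyVector = FALSE)
  }
}

write_structured_document <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, null = "null",
                                digits = NA), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
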