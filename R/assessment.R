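HOUSING_TYPES <- c("collective", "individual")
SETTINGS <- c("urban", "rural")
TENURES <- c("owner_occupant", "private_rental", "social_housing")
META_FIELDS <- c("housing_type", "setting", "overseas", "tenure", "typology")
# schema-level PII prohibition: a dwelling assessment is anonymous by design
PII_FIELDS <- c("name", "first_name", "last_name", "surname", "occupant_name",
                "address", "street", "postcode", "zip", "email", "phone",
                "telephone", "id_number", "birth_date")

#' Construct a dwelling assessment
#'
#' One filled-out grid for one dwelling visit. Each grid variable is either
#' scored on the 0 (most favorable) to 3 (most unfavorable) ordinal scale or
#' left unscored with a reason (`data_unavailable`, `site_inaccessible`,
#' `diagnosis_unavailable`, `description_unclear`, `other`). Assessments are
#' anonymous: no field naming a person or an address is accepted.
#'
#' @param grid_version Version tag of the grid the assessment was filled
#'   against.
#' @param entries Named list mapping variable id to either an integer score
#'   in 0--3 or a missing-reason string.
#' @param dwelling_meta List with any of `housing_type`
#'   (`collective`/`individual`), `setting` (`urban`/`rural`), `overseas`
#'   (logical), `tenure` (`owner_occupant`/`private_rental`/`social_housing`),
#'   `typology` (free text).
#' @param vulnerabilities Character vector drawn from the five occupant
#'   vulnerability kinds (see [load_matrix()]).
#' @param visit_meta Optional list of timings in minutes:
#'   `minutes_before`, `minutes_during`, `minutes_after`.
#' @return Object of class `domiscore_assessment`.
#' @export
#' @examples
#' a <- assessment("2020-11",
#'                 entries = list(ventilation = 2, mold = "data_unavailable"))
assessment <- function(grid_version, entries, dwelling_meta = list(),
                       vulnerabilities = character(0), visit_meta = NULL) {
  if (length(entries) && is.null(names(entries))) {
    stop("entries must be named by variable id", call. = FALSE)
  }
  a <- structure(
    list(grid_version = as.character(grid_version),
         entries = as.list(entries),
         dwelling_meta = as.list(dwelling_meta),
         vulnerabilities = as.character(vulnerabilities),
         visit_meta = visit_meta),
    class = "domiscore_assessment")
  check_assessment_shape(a)
  a
}

# structural checks that need no grid
check_assessment_shape <- function(a) {
  for (id in names(a$entries)) {
    e <- a$entries[[id]]
    if (is.numeric(e)) {
      if (length(e) != 1L || is.na(e) || e != as.integer(e) || e < 0 || e > 3) {
        stop("entry '", id, "': scores must be single integers in 0-3 (got ",
             deparse(e), ")", call. = FALSE)
      }
    } else if (is.character(e)) {
      if (!(e %in% MISSING_REASONS)) {
        stop("entry '", id, "': unknown missing reason '", e, "'", call. = FALSE)
      }
    } else {
      stop("entry '", id, "': must be a score in 0-3 or a missing-reason string",
           call. = FALSE)
    }
  }
  bad <- setdiff(a$vulnerabilities, VULNERABILITIES)
  if (length(bad)) {
    stop("unknown vulnerability kind(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  pii <- intersect(tolower(names(a$dwelling_meta)), PII_FIELDS)
  if (length(pii)) {
    stop("assessment carries prohibited identifying field(s): ",
         paste(pii, collapse = ", "), call. = FALSE)
  }
  m <- a$dwelling_meta
  if (!is.null(m$housing_type) && !(m$housing_type %in% HOUSING_TYPES)) {
    stop("dwelling_meta$housing_type must be one of: ",
         paste(HOUSING_TYPES, collapse = ", "), call. = FALSE)
  }
  if (!is.null(m$setting) && !(m$setting %in% SETTINGS)) {
    stop("dwelling_meta$setting must be one of: ", paste(SETTINGS, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(m$tenure) && !(m$tenure %in% TENURES)) {
    stop("dwelling_meta$tenure must be one of: ", paste(TENURES, collapse = ", "),
         call. = FALSE)
  }
  invisible(a)
}

#' Validate an assessment against a grid
#'
#' @param a A `domiscore_assessment`.
#' @param grid A `domiscore_grid`.
#' @param check_version Error when the assessment's `grid_version` differs
#'   from the grid's (default `TRUE`).
#' @return `a`, invisibly; errors describe the offending entry.
#' @export
validate_assessment <- function(a, grid, check_version = TRUE) {
  stopifnot(inherits(a, "domiscore_assessment"), inherits(grid, "domiscore_grid"))
  check_assessment_shape(a)
  if (check_version && !identical(a$grid_version, grid$version)) {
    stop("assessment grid_version '", a$grid_version,
         "' does not match grid version '", grid$version, "'", call. = FALSE)
  }
  unknown <- setdiff(names(a$entries), grid_variable_ids(grid))
  if (length(unknown)) {
    stop("assessment references unknown variable id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(a)
}

# numeric scores named by variable id, NA when missing/unscored, in grid order
assessment_scores <- function(a, grid) {
  ids <- grid_variable_ids(grid)
  s <- rep(NA_integer_, length(ids))
  names(s) <- ids
  for (id in intersect(names(a$entries), ids)) {
    e <- a$entries[[id]]
    if (is.numeric(e)) s[[id]] <- as.integer(e)
  }
  s
}

#' @export
print.domiscore_assessment <- function(x, ...) {
  ns <- sum(vapply(x$entries, is.numeric, logical(1)))
  nm <- length(x$entries) - ns
  cat("Domiscore assessment (grid ", x$grid_version, "): ",
      ns, " scored, ", nm, " unscored variable entries\n", sep = "")
  if (length(x$vulnerabilities)) {
    cat("  occupant vulnerabilities: ", paste(x$vulnerabilities, collapse = ", "), "\n", sep = "")
  }
  m <- x$dwelling_meta
  if (length(m)) {
    cat("  dwelling: ", paste(names(m), unlist(lapply(m, as.character)),
                              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

## ------------------------------------------------------------------
## document I/O

#' Read and write single assessments as structured documents
#'
#' JSON is the standard encoding (YAML accepted by extension). Documents
#' containing identifying fields are rejected on read.
#'
#' @param source Path to an assessment document or a parsed list.
#' @return [read_assessment()] returns a `domiscore_assessment`.
#' @export
read_assessment <- function(source) {
  doc <- read_structured_document(source)
  extra <- intersect(tolower(names(doc)), PII_FIELDS)
  if (length(extra)) {
    stop("assessment document carries prohibited identifying field(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  entries <- lapply(doc$entries, function(e) {
    if (is.character(e)) e else as.integer(e)
  })
  assessment(grid_version = doc$grid_version %||% stop("assessment lacks grid_version", call. = FALSE),
             entries = entries,
             dwelling_meta = doc$dwelling_meta %||% list(),
             vulnerabilities = as.character(unlist(doc$vulnerabilities)),
             visit_meta = doc$visit_meta)
}

#' @rdname read_assessment
#' @param a A `domiscore_assessment`.
#' @param path Output file path.
#' @export
write_assessment <- function(a, path) {
  stopifnot(inherits(a, "domiscore_assessment"))
  write_structured_document(unclass(a), path)
  invisible(path)
}

## ------------------------------------------------------------------
## batch CSV: one row per dwelling, one column per variable id
## (values 0-3 or a missing-reason code), metadata and vulnerability columns

batch_header <- function(grid) {
  c("row_id", grid_variable_ids(grid), META_FIELDS,
    paste0("vuln_", VULNERABILITIES))
}

#' Read a batch of assessments from CSV
#'
#' The batch format has a mandatory header, one row per dwelling, one column
#' per grid variable id holding the score 0--3 or a missing-reason code
#' (never an empty cell), dwelling metadata columns (`housing_type`,
#' `setting`, `overseas`, `tenure`, `typology`) and one 0/1 column per
#' vulnerability kind (`vuln_young_children_u4`, ...).
#'
#' @param path CSV file path.
#' @param grid A `domiscore_grid`; variable columns are matched to its ids.
#' @return List of `domiscore_assessment` objects.
#' @export
read_assessment_batch <- function(path, grid) {
  stopifnot(inherits(grid, "domiscore_grid"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  ids <- intersect(grid_variable_ids(grid), names(df))
  if (!length(ids)) stop("batch CSV has no column matching a grid variable id", call. = FALSE)
  vcols <- intersect(paste0("vuln_", VULNERABILITIES), names(df))
  lapply(seq_len(nrow(df)), function(i) {
    entries <- list()
    for (id in ids) {
      val <- df[[id]][i]
      if (is.na(val) || !nzchar(val)) {
        stop("row ", i, ", variable '", id,
             "': empty cell; use a score 0-3 or a missing-reason code", call. = FALSE)
      }
      entries[[id]] <- if (val %in% MISSING_REASONS) val else {
        num <- suppressWarnings(as.numeric(val))
        if (is.na(num)) {
          stop("row ", i, ", variable '", id, "': unrecognized value '", val, "'",
               call. = FALSE)
        }
        num
      }
    }
    meta <- list()
    for (f in intersect(META_FIELDS, names(df))) {
      val <- df[[f]][i]
      if (!is.na(val) && nzchar(val)) {
        meta[[f]] <- if (f == "overseas") as.logical(toupper(val) %in% c("TRUE", "1")) else val
      }
    }
    vuln <- sub("^vuln_", "", vcols[vapply(vcols, function(cl) df[[cl]][i] %in% c("1", "TRUE", "true"), logical(1))])
    assessment(grid$version, entries, dwelling_meta = meta, vulnerabilities = vuln)
  })
}

#' @rdname read_assessment_batch
#' @param assessments List of `domiscore_assessment` objects.
#' @export
write_assessment_batch <- function(assessments, path, grid) {
  stopifnot(inherits(grid, "domiscore_grid"))
  ids <- grid_variable_ids(grid)
  rows <- lapply(seq_along(assessments), function(i) {
    a <- assessments[[i]]
    cells <- vapply(ids, function(id) {
      e <- a$entries[[id]]
      if (is.null(e)) "data_unavailable" else as.character(e)
    }, "")
    meta <- vapply(META_FIELDS, function(f) {
      v <- a$dwelling_meta[[f]]
      if (is.null(v)) "" else as.character(v)
    }, "")
    vuln <- vapply(VULNERABILITIES, function(v) {
      if (v %in% a$vulnerabilities) "1" else "0"
    }, "")
    c(row_id = as.character(i), cells, meta, vuln)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- batch_header(grid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
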