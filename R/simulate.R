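# defaults echo the 28-visit test phase: 71% urban, 68% collective,
# 68% metropolitan (32% overseas), tenure 46/32/22 private/social/owner;
# 9% overall missingness dominated by data unavailability
DEFAULT_META_MIX <- list(
  housing_type = c(collective = 0.68, individual = 0.32),
  setting = c(urban = 0.71, rural = 0.29),
  overseas = 0.32,
  tenure = c(private_rental = 0.46, social_housing = 0.32, owner_occupant = 0.22)
)
DEFAULT_REASON_WEIGHTS <- c(data_unavailable = 3, diagnosis_unavailable = 2,
                            site_inaccessible = 2, description_unclear = 1,
                            other = 1)
DEFAULT_VULN_PREVALENCE <- c(young_children_u4 = 0.15, elderly_o70 = 0.15,
                             physical_disability = 0.05, visual_disability = 0.03,
                             hearing_disability = 0.03)

#' Define a dwelling quality profile for simulation
#'
#' A profile drives the synthetic generator: per-variable score
#' probabilities over the ordinal levels 0--3, a missingness probability
#' (with reasons drawn from configurable weights), per-vulnerability
#' prevalence, and the dwelling metadata mixture. Three named presets are
#' built in: `"favorable"` (mass concentrated on 0), `"mixed"` and
#' `"degraded"` (mass concentrated on 3). Metadata and missingness defaults
#' mirror the proportions observed in the instrument's 28-visit test phase.
#'
#' @param name Preset name (`"favorable"`, `"mixed"`, `"degraded"`) or a
#'   free label when `level_weights` is supplied.
#' @param level_weights Numeric length-4 probability weights over scores
#'   0..3; overrides the preset.
#' @param missingness Probability a variable is left unscored (default
#'   0.09).
#' @param reason_weights Named weights over the five missing reasons.
#' @param vulnerability_prevalence Named probabilities per vulnerability
#'   kind.
#' @param meta_mix List of probability vectors for `housing_type`,
#'   `setting`, `tenure` and a scalar `overseas` probability.
#' @param category_correlation Nonnegative scalar; when positive, a shared
#'   latent severity per category tilts its variables' level weights up or
#'   down together (real deficiencies cluster by theme). 0 = independent
#'   variables (default).
#' @return Object of class `quality_profile`.
#' @export
quality_profile <- function(name = c("mixed", "favorable", "degraded"),
                            level_weights = NULL,
                            missingness = 0.09,
                            reason_weights = DEFAULT_REASON_WEIGHTS,
                            vulnerability_prevalence = DEFAULT_VULN_PREVALENCE,
                            meta_mix = DEFAULT_META_MIX,
                            category_correlation = 0) {
  if (is.null(level_weights)) {
    name <- match.arg(name)
    level_weights <- switch(name,
      favorable = c(0.70, 0.20, 0.08, 0.02),
      mixed = c(0.40, 0.30, 0.20, 0.10),
      degraded = c(0.10, 0.20, 0.30, 0.40))
  } else {
    name <- as.character(name)[1L]
  }
  level_weights <- as.numeric(level_weights)
  if (length(level_weights) != 4L || any(level_weights < 0) || sum(level_weights) <= 0) {
    stop("level_weights must be 4 nonnegative weights with positive sum", call. = FALSE)
  }
  level_weights <- level_weights / sum(level_weights)
  if (missingness < 0 || missingness > 1) stop("missingness must be in [0,1]", call. = FALSE)
  if (any(vulnerability_prevalence < 0) || any(vulnerability_prevalence > 1)) {
    stop("vulnerability prevalences must be in [0,1]", call. = FALSE)
  }
  if (category_correlation < 0) stop("category_correlation must be >= 0", call. = FALSE)
  structure(list(name = name, level_weights = level_weights,
                 missingness = missingness,
                 reason_weights = reason_weights / sum(reason_weights),
                 vulnerability_prevalence = vulnerability_prevalence,
                 meta_mix = meta_mix,
                 category_correlation = category_correlation),
            class = "quality_profile")
}

#' @export
print.quality_profile <- function(x, ...) {
  cat("Quality profile '", x$name, "': P(score)=",
      paste(sprintf("%.2f", x$level_weights), collapse = "/"),
      ", missingness ", sprintf("%.0f%%", 100 * x$missingness), "\n", sep = "")
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Generate one synthetic dwelling assessment
#'
#' Draws one entry per grid variable (scored with the profile's level
#' weights, or unscored with a reason), occupant vulnerabilities, and
#' dwelling metadata. Fully deterministic given `(grid, profile, seed)`.
#'
#' @param grid A `domiscore_grid`.
#' @param profile A `quality_profile`.
#' @param seed Integer seed.
#' @return A `domiscore_assessment`.
#' @export
#' @examples
#' g <- load_grid(domiscore_grid_file("2020-11"))
#' a <- generate_assessment(g, quality_profile("degraded"), seed = 1)
generate_assessment <- function(grid, profile, seed) {
  stopifnot(inherits(grid, "domiscore_grid"), inherits(profile, "quality_profile"))
  with_seed(seed, {
    ids <- grid_variable_ids(grid)
    cat_of <- vapply(grid$variables, `[[`, "", "category_id")
    # optional shared latent severity per category: tilt weights by exp(z*level)
    tilt <- stats::setNames(rep(0, length(grid$categories)), grid_category_ids(grid))
    if (profile$category_correlation > 0) {
      tilt[] <- stats::rnorm(length(tilt), 0, profile$category_correlation)
    }
    entries <- list()
    for (i in seq_along(ids)) {
      if (stats::runif(1) < profile$missingness) {
        entries[[ids[i]]] <- sample(names(profile$reason_weights), 1L,
                                    prob = profile$reason_weights)
      } else {
        w <- profile$level_weights * exp(tilt[[cat_of[i]]] * (0:3))
        entries[[ids[i]]] <- sample(0:3, 1L, prob = w / sum(w))
      }
    }
    vp <- profile$vulnerability_prevalence
    vuln <- names(vp)[stats::runif(length(vp)) < vp]
    mm <- profile$meta_mix
    meta <- list(
      housing_type = sample(names(mm$housing_type), 1L, prob = mm$housing_type),
      setting = sample(names(mm$setting), 1L, prob = mm$setting),
      overseas = stats::runif(1) < mm$overseas,
      tenure = sample(names(mm$tenure), 1L, prob = mm$tenure)
    )
    assessment(grid$version, entries, dwelling_meta = meta, vulnerabilities = vuln)
  })
}

#' Specify a synthetic housing stock
#'
#' @param n_dwellings Number of dwellings (>= 1).
#' @param profiles List of `quality_profile` objects (or a single one).
#' @param weights Mixture weights over `profiles` (default uniform).
#' @param seed Integer master seed; per-dwelling seeds are derived from it.
#' @return Object of class `stock_spec`.
#' @export
stock_spec <- function(n_dwellings, profiles = list(quality_profile("mixed")),
                       weights = NULL, seed = 1L) {
  if (inherits(profiles, "quality_profile")) profiles <- list(profiles)
  stopifnot(all(vapply(profiles, inherits, logical(1), "quality_profile")))
  n_dwellings <- as.integer(n_dwellings)
  if (is.na(n_dwellings) || n_dwellings < 1L) stop("n_dwellings must be >= 1", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(profiles))
  if (length(weights) != length(profiles) || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be nonnegative, one per profile, with positive sum", call. = FALSE)
  }
  structure(list(n_dwellings = n_dwellings, profiles = profiles,
                 weights = weights / sum(weights), seed = as.integer(seed)),
            class = "stock_spec")
}

# stable multiplicative hash for per-dwelling seeds, mod the Mersenne prime
# 2^31-1; dwelling i's seed does not depend on n, so stocks extend without
# reshuffling (doubles are exact here: products stay below 2^53)
derive_seed <- function(seed, i) {
  m <- 2147483647
  s <- ((seed %% m) * 48271 + i * 16807) %% m
  as.integer(s)
}

#' Generate a synthetic housing stock
#'
#' Draws `n_dwellings` assessments. Each dwelling's profile is chosen from
#' the spec's mixture and its scores are drawn under a seed derived
#' deterministically from the master seed and the dwelling index, so the
#' same spec always yields the same stock and a longer stock extends a
#' shorter one.
#'
#' @param grid A `domiscore_grid`.
#' @param spec A `stock_spec`.
#' @return List of `domiscore_assessment` objects with attribute
#'   `profile_index` (which mixture component generated each dwelling).
#' @export
generate_stock <- function(grid, spec) {
  stopifnot(inherits(grid, "domiscore_grid"), inherits(spec, "stock_spec"))
  idx <- integer(spec$n_dwellings)
  out <- vector("list", spec$n_dwellings)
  for (i in seq_len(spec$n_dwellings)) {
    si <- derive_seed(spec$seed, i)
    k <- with_seed(si, sample(seq_along(spec$profiles), 1L, prob = spec$weights))
    idx[i] <- k
    out[[i]] <- generate_assessment(grid, spec$profiles[[k]], seed = derive_seed(si, 1L))
  }
  attr(out, "profile_index") <- idx
  out
}
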