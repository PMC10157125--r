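# In-code fixtures: tiny grids, random grids/assessments/matrices, and an
# independent brute-force scoring oracle written with explicit loops.

levels_stub <- function() {
  as.list(setNames(paste("level", 0:3), as.character(0:3)))
}

# categories: named list, name = category id, value = character vector of
# variable ids; alerts: named list variable_id -> threshold
make_grid <- function(categories, alerts = list(), version = "test-1") {
  vars <- list()
  pos <- 0L
  for (cid in names(categories)) {
    for (vid in categories[[cid]]) {
      pos <- pos + 1L
      vars[[pos]] <- list(id = vid, label = vid, category_id = cid,
                          position = pos, sources = list("in_situ"),
                          level_descriptions = levels_stub(),
                          alert_threshold = alerts[[vid]], notes = "")
    }
  }
  cats <- lapply(names(categories), function(cid) {
    list(id = cid, label = cid, variable_ids = as.list(categories[[cid]]))
  })
  validate_grid(list(schema_version = 1, version = version,
                     categories = cats, variables = vars))
}

make_matrix <- function(rules, grid_version = "test-1") {
  load_matrix(list(grid_version = grid_version,
                   rules = lapply(rules, function(r) {
                     list(vulnerability = r[[1]], variable_id = r[[2]],
                          trigger_threshold = r[[3]], penalty_points = 1L)
                   })))
}

all_vulns <- c("young_children_u4", "elderly_o70", "physical_disability",
               "visual_disability", "hearing_disability")
all_reasons <- c("data_unavailable", "site_inaccessible", "diagnosis_unavailable",
                 "description_unclear", "other")

random_grid <- function(seed) {
  set.seed(seed)
  n_cat <- sample(2:6, 1)
  cats <- list()
  v <- 0L
  alerts <- list()
  for (k in seq_len(n_cat)) {
    n_var <- sample(1:4, 1)
    ids <- paste0("v", v + seq_len(n_var))
    v <- v + n_var
    cats[[paste0("c", k)]] <- ids
    for (id in ids) {
      if (runif(1) < 0.3) alerts[[id]] <- sample(1:3, 1)
    }
  }
  make_grid(cats, alerts, version = paste0("rg-", seed))
}

random_assessment <- function(grid, seed, p_missing = 0.2, p_vuln = 0.3) {
  set.seed(seed + 7L)
  ids <- vapply(grid$variables, `[[`, "", "id")
  entries <- list()
  for (id in ids) {
    entries[[id]] <- if (runif(1) < p_missing) sample(all_reasons, 1) else sample(0:3, 1)
  }
  vuln <- all_vulns[runif(5) < p_vuln]
  assessment(grid$version, entries, vulnerabilities = vuln)
}

random_matrix <- function(grid, seed) {
  set.seed(seed + 13L)
  ids <- vapply(grid$variables, `[[`, "", "id")
  rules <- list()
  for (v in all_vulns) {
    for (id in ids) {
      if (runif(1) < 0.25) rules[[length(rules) + 1L]] <- list(v, id, sample(1:3, 1))
    }
  }
  if (!length(rules)) rules[[1]] <- list("elderly_o70", ids[1], 2L)
  make_matrix(rules, grid_version = grid$version)
}

# Independent recomputation: explicit max/sum/penalty/threshold loops over
# the raw documents; shares nothing with the engine's scoring path.
oracle_score <- function(a, grid, matrix = NULL, penalty_mode = "single_mean") {
  ids <- vapply(grid$variables, `[[`, "", "id")
  raw <- list()
  for (id in ids) {
    e <- a$entries[[id]]
    if (!is.null(e) && is.numeric(e)) raw[[id]] <- as.integer(e)
  }
  adj <- raw
  if (!is.null(matrix)) {
    for (k in seq_len(nrow(matrix$rules))) {
      vul <- matrix$rules$vulnerability[k]
      vid <- matrix$rules$variable_id[k]
      thr <- matrix$rules$trigger_threshold[k]
      if (vul %in% a$vulnerabilities && !is.null(raw[[vid]]) && raw[[vid]] >= thr) {
        adj[[vid]] <- adj[[vid]] + 1L
      }
    }
  }
  cat_scores <- c()
  n_blank <- 0L
  for (cc in grid$categories) {
    best <- NULL
    for (vid in unlist(cc$variable_ids)) {
      if (!is.null(adj[[vid]])) {
        if (is.null(best) || adj[[vid]] > best) best <- adj[[vid]]
      }
    }
    if (is.null(best)) n_blank <- n_blank + 1L else cat_scores <- c(cat_scores, best)
  }
  if (!length(cat_scores)) stop("oracle: all categories blank")
  raw_sum <- sum(cat_scores)
  pen <- 0
  if (n_blank > 0L) {
    pen <- raw_sum / length(cat_scores)
    if (penalty_mode == "mean_per_blank") pen <- pen * n_blank
  }
  total <- raw_sum + pen
  global <- floor(total + 0.5 + 1e-9)  # half away from zero on nonnegatives
  base <- floor(length(grid$categories) / 2) + 1
  cls <- if (global < base) "green" else if (global < 2 * base) "yellow" else
    if (global < 3 * base) "orange" else "red"
  alerts <- character(0)
  for (v in grid$variables) {
    if (!is.null(v$alert_threshold) && !is.null(adj[[v$id]]) &&
        adj[[v$id]] >= v$alert_threshold) {
      alerts <- c(alerts, v$id)
    }
  }
  list(raw_sum = raw_sum, penalty = pen, global = as.integer(global),
       class = cls, n_blank = n_blank, alerts = alerts,
       completion = length(raw) / length(ids))
}

grid_ids <- function(grid) vapply(grid$variables, `[[`, "", "id")

complete_assessment <- function(grid, score) {
  ids <- grid_ids(grid)
  assessment(grid$version, setNames(as.list(rep(score, length(ids))), ids))
}
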