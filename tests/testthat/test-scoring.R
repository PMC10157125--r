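test_that("vulnerability penalties fire at the trigger threshold, on pre-penalty scores", {
  g <- load_grid(domiscore_grid_file("2020-11"))
  m <- load_matrix(domiscore_matrix_file())

  a <- assessment("2020-11", list(ventilation = 3), vulnerabilities = "young_children_u4")
  expect_identical(apply_vulnerability_penalties(a, m, g)[["ventilation"]], 4L)

  # below the trigger the rule cannot fire
  a2 <- assessment("2020-11", list(ventilation = 2), vulnerabilities = "young_children_u4")
  expect_identical(apply_vulnerability_penalties(a2, m, g)[["ventilation"]], 2L)

  # surface area with visual disability triggers at 1
  a3 <- assessment("2020-11", list(surface_area = 1), vulnerabilities = "visual_disability")
  expect_identical(apply_vulnerability_penalties(a3, m, g)[["surface_area"]], 2L)
  a4 <- assessment("2020-11", list(surface_area = 0), vulnerabilities = "visual_disability")
  expect_identical(apply_vulnerability_penalties(a4, m, g)[["surface_area"]], 0L)

  # no vulnerabilities: identity
  a5 <- assessment("2020-11", list(ventilation = 3, surface_area = 1))
  adj <- apply_vulnerability_penalties(a5, m, g)
  expect_identical(adj[["ventilation"]], 3L)
  expect_identical(adj[["surface_area"]], 1L)

  # unscored variables stay unscored
  expect_true(is.na(adj[["mold"]]))
})

test_that("distinct vulnerabilities stack on one variable without cascading", {
  g <- make_grid(list(c1 = "x"))
  m <- make_matrix(list(list("elderly_o70", "x", 2L),
                        list("visual_disability", "x", 2L),
                        # would only fire if penalties cascaded off adjusted scores
                        list("hearing_disability", "x", 3L)))
  a <- assessment("test-1", list(x = 2),
                  vulnerabilities = c("elderly_o70", "visual_disability",
                                      "hearing_disability"))
  expect_identical(apply_vulnerability_penalties(a, m, g)[["x"]], 4L)
})

test_that("thematic score is the maximum over scored variables only", {
  g <- make_grid(list(c1 = c("a", "b", "c"), c2 = c("d", "e")))
  th <- thematic_scores(c(a = 0L, b = 1L, c = 3L, d = NA, e = NA), g)
  expect_identical(th$score, c(3L, NA_integer_))
  expect_identical(th$color, c("red", NA_character_))
  expect_identical(th$blank, c(FALSE, TRUE))

  th2 <- thematic_scores(c(a = 2L, b = NA, c = 1L), g)
  expect_identical(th2$score[1], 2L)
  # ties: first variable in grid order attaining the maximum
  th3 <- thematic_scores(c(a = 2L, b = 2L, c = 0L), g)
  expect_identical(th3$contributing_variable[1], "a")
})

test_that("color mapping follows the quadri-chromatic code, red open above", {
  expect_identical(score_color(0:4), c("green", "yellow", "orange", "red", "red"))
})

test_that("missing-data penalty is the mean of completed thematic scores", {
  # 12 completed categories summing to 18, 3 blank -> 18/12 = 1.5
  g <- make_grid(setNames(as.list(paste0("v", 1:15)), paste0("c", 1:15)))
  sc <- setNames(c(rep(c(1L, 2L), 6), rep(NA_integer_, 3)), paste0("v", 1:15))
  th <- thematic_scores(sc, g)
  pen <- missing_penalty(th)
  expect_identical(pen$numerator, 18L)
  expect_identical(pen$denominator, 12L)
  expect_identical(pen$value, 1.5)

  # no blank categories -> 0
  full <- thematic_scores(setNames(rep(2L, 15), paste0("v", 1:15)), g)
  expect_identical(missing_penalty(full)$value, 0)

  # completed categories all 0, one blank -> 0
  zero <- thematic_scores(setNames(c(rep(0L, 14), NA), paste0("v", 1:15)), g)
  expect_identical(missing_penalty(zero)$value, 0)

  # mean_per_blank adds the mean once per blank category
  expect_identical(missing_penalty(th, "mean_per_blank")$value, 4.5)

  # all blank: unscorable
  blank <- thematic_scores(setNames(rep(NA_integer_, 15), paste0("v", 1:15)), g)
  expect_error(missing_penalty(blank), "unscorable")
})

test_that("global score adds the penalty and rounds half away from zero", {
  g <- make_grid(setNames(as.list(paste0("v", 1:15)), paste0("c", 1:15)))
  entries <- setNames(c(as.list(rep(c(1, 2), 6)), as.list(rep("data_unavailable", 3))),
                      paste0("v", 1:15))
  r <- domiscore(assessment("test-1", entries), g)
  expect_identical(r$raw_sum, 18L)
  expect_identical(r$penalty_fraction, "18/12")
  expect_identical(r$global_score, 20L)  # 18 + 1.5 rounds up
  expect_identical(r$n_blank, 3L)
  expect_identical(r$n_completed, 12L)
})

test_that("class boundaries generalize (floor(n/2)+1) * k", {
  expect_identical(class_boundaries(15)$lower_bounds,
                   c(yellow = 8L, orange = 16L, red = 24L))
  expect_identical(class_boundaries(16)$lower_bounds,
                   c(yellow = 9L, orange = 18L, red = 27L))
  expect_identical(class_boundaries(1)$lower_bounds,
                   c(yellow = 1L, orange = 2L, red = 3L))
  expect_error(class_boundaries(0), ">= 1")
})

test_that("classification reproduces the printed 15-theme ranges over 0-60", {
  for (x in 0:60) {
    expected <- if (x <= 7) "green" else if (x <= 15) "yellow" else
      if (x <= 23) "orange" else "red"
    expect_identical(classify_score(x, 15), expected)
  }
  expect_error(classify_score(-1, 15), "nonnegative")
})

test_that("complete floor and ceiling assessments hit the published bounds", {
  g15 <- load_grid(domiscore_grid_file("2020-01"))
  g16 <- load_grid(domiscore_grid_file("2020-11"))

  r0 <- domiscore(complete_assessment(g15, 0), g15)
  expect_identical(r0$global_score, 0L)
  expect_identical(r0$equivalence_class, "green")
  expect_identical(nrow(r0$alerts), 0L)
  expect_identical(r0$completion_rate, 1)

  r45 <- domiscore(complete_assessment(g15, 3), g15)
  expect_identical(r45$global_score, 45L)
  expect_identical(r45$equivalence_class, "red")

  r48 <- domiscore(complete_assessment(g16, 3), g16)
  expect_identical(r48$global_score, 48L)
  expect_identical(r48$equivalence_class, "red")
})

test_that("alerts fire at or above the variable threshold and never stop scoring", {
  g <- make_grid(list(c1 = c("a", "b")), alerts = list(a = 2L))
  al <- detect_alerts(c(a = 2L, b = 3L), g)
  expect_identical(al$variable_id, "a")
  expect_identical(detect_alerts(c(a = 1L, b = 3L), g)$variable_id, character(0))
  g2 <- make_grid(list(c1 = c("a", "b")))
  expect_identical(nrow(detect_alerts(c(a = 3L, b = 3L), g2)), 0L)
  # a result is still produced when an alert fires
  r <- domiscore(assessment("test-1", list(a = 3, b = 0)), g)
  expect_identical(nrow(r$alerts), 1L)
  expect_identical(r$global_score, 3L)
})

test_that("all-blank assessments are unscorable, not zero", {
  g <- make_grid(list(c1 = c("a", "b")))
  a <- assessment("test-1", list(a = "data_unavailable", b = "site_inaccessible"))
  expect_error(domiscore(a, g), "unscorable")
})

test_that("a version mismatch between assessment and grid is an error", {
  g <- make_grid(list(c1 = "a"), version = "test-1")
  a <- assessment("other", list(a = 1))
  expect_error(domiscore(a, g), "version")
})

test_that("vulnerability penalties can push a theme past red and past 3n overall", {
  g <- make_grid(list(c1 = "x"))
  m <- make_matrix(list(list("elderly_o70", "x", 3L)))
  r <- domiscore(assessment("test-1", list(x = 3), vulnerabilities = "elderly_o70"),
                 g, m)
  expect_identical(r$thematic$score, 4L)
  expect_identical(r$thematic$color, "red")
  expect_identical(r$global_score, 4L)   # above 3 * n_themes = 3
  expect_identical(r$equivalence_class, "red")
})
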