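g16 <- load_grid(domiscore_grid_file("2020-11"))

test_that("completion rate is the scored fraction of grid variables", {
  ids <- grid_ids(g16)
  full <- complete_assessment(g16, 1)
  expect_identical(completion_rate(full, g16), 1)

  entries <- setNames(c(as.list(rep(1, 42)), as.list(rep("data_unavailable", 4))), ids)
  part <- assessment("2020-11", entries)
  expect_equal(completion_rate(part, g16), 42 / 46)

  none <- assessment("2020-11", setNames(as.list(rep("other", 46)), ids))
  expect_identical(completion_rate(none, g16), 0)
})

test_that("stock summaries satisfy their conservation invariants", {
  stock <- generate_stock(g16, stock_spec(40, list(quality_profile("favorable"),
                                                   quality_profile("degraded")),
                                          seed = 9))
  results <- lapply(stock, domiscore, grid = g16)
  s <- summarize_stock(results)
  expect_identical(sum(s$class_counts), 40L)
  expect_identical(s$n_dwellings, 40L)
  expect_true(all(rowSums(s$theme_color_frequencies) == 40))
  expect_identical(nrow(s$theme_color_frequencies), 16L)
})

test_that("stock summary equals an independent recomputation on a mixed stock", {
  n <- 500
  stock <- generate_stock(g16, stock_spec(n, list(quality_profile("favorable"),
                                                  quality_profile("mixed"),
                                                  quality_profile("degraded")),
                                          seed = 77))
  results <- lapply(stock, domiscore, grid = g16)
  s <- summarize_stock(results)
  # raw per-dwelling re-aggregation
  gs <- sapply(results, function(r) r$global_score)
  cr <- sapply(results, function(r) r$completion_rate)
  cls <- sapply(results, function(r) r$equivalence_class)
  expect_identical(s$n_dwellings, as.integer(n))
  expect_equal(unname(s$global_score_stats),
               c(mean(gs), sd(gs), min(gs), max(gs)))
  expect_equal(unname(s$completion_stats), c(mean(cr), sd(cr)))
  for (k in c("green", "yellow", "orange", "red")) {
    expect_identical(s$class_counts[[k]], as.integer(sum(cls == k)))
  }
  expect_identical(s$alert_count, as.integer(sum(sapply(results, function(r) nrow(r$alerts)))))
  # per-theme color recount for one theme
  col1 <- sapply(results, function(r) if (r$thematic$blank[1]) "blank" else r$thematic$color[1])
  expect_identical(unname(s$theme_color_frequencies[1, ]),
                   as.integer(table(factor(col1, levels = c("green", "yellow", "orange",
                                                            "red", "blank")))))
})

test_that("aggregation is permutation-invariant and degenerate cases are flagged", {
  stock <- generate_stock(g16, stock_spec(12, quality_profile("mixed"), seed = 4))
  results <- lapply(stock, domiscore, grid = g16)
  s1 <- summarize_stock(results)
  s2 <- summarize_stock(rev(results))
  expect_equal(s1, s2)

  # identical results: SD 0, one class holds everything
  same <- replicate(5, results[[1]], simplify = FALSE)
  ss <- summarize_stock(same)
  expect_identical(unname(ss$global_score_stats[["sd"]]), 0)
  expect_identical(max(ss$class_counts), 5L)

  # singleton: mean = value, SD undefined
  one <- summarize_stock(results[1])
  expect_identical(unname(one$global_score_stats[["mean"]]),
                   as.numeric(results[[1]]$global_score))
  expect_true(is.na(one$global_score_stats[["sd"]]))

  expect_error(summarize_stock(list()), "no results")
})

test_that("mixed grid versions cannot be aggregated", {
  g15 <- load_grid(domiscore_grid_file("2020-01"))
  r16 <- domiscore(complete_assessment(g16, 1), g16)
  r15 <- domiscore(complete_assessment(g15, 1), g15)
  expect_error(summarize_stock(list(r16, r15)), "mixed grid versions")
})

test_that("repeat-visit comparison counts agreement over commonly scored variables", {
  ids <- grid_ids(g16)
  base <- setNames(as.list(rep(1, 46)), ids)
  a <- assessment("2020-11", base)

  # identical assessments: full agreement, zero deltas
  rep0 <- compare_assessments(a, a, g16)
  expect_identical(rep0$exact_agreement, 1)
  expect_identical(rep0$global_score_delta, 0L)
  expect_true(all(rep0$per_category_score_delta == 0))

  # differ on 5 of 40 commonly scored variables
  b_entries <- base
  for (id in ids[1:3]) b_entries[[id]] <- "data_unavailable"    # unscored in b
  b <- assessment("2020-11", b_entries)
  a_entries <- base
  for (id in ids[44:46]) a_entries[[id]] <- "site_inaccessible" # unscored in a
  for (id in ids[7:11]) a_entries[[id]] <- 3                    # 5 disagreements
  a2 <- assessment("2020-11", a_entries)
  rep1 <- compare_assessments(a2, b, g16)
  expect_identical(rep1$n_compared_variables, 40L)
  expect_equal(rep1$exact_agreement, 35 / 40)

  # symmetry: deltas flip sign, agreement unchanged
  rep2 <- compare_assessments(b, a2, g16)
  expect_identical(rep1$exact_agreement, rep2$exact_agreement)
  expect_identical(rep1$global_score_delta, -rep2$global_score_delta)

  # disjoint scored sets: agreement undefined
  left <- assessment("2020-11", setNames(c(list(1), as.list(rep("other", 45))), ids))
  right <- assessment("2020-11", setNames(c(list("other", 1), as.list(rep("other", 44))), ids))
  rep3 <- compare_assessments(left, right, g16)
  expect_identical(rep3$n_compared_variables, 0L)
  expect_true(is.na(rep3$exact_agreement))
})

test_that("version mismatch in comparison is an error", {
  g15 <- load_grid(domiscore_grid_file("2020-01"))
  a <- complete_assessment(g16, 1)
  b <- complete_assessment(g15, 1)
  expect_error(compare_assessments(a, b, g16), "different grid versions")
})
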