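test_that("the full factorial design enumerates every situation once", {
  d <- full_design(design_grid())
  expect_identical(nrow(d), 875L)
  expect_identical(anyDuplicated(d[c("n0", "travel_time", "p_natal", "cost")]),
                   0L)
  # documented order: n0 varies fastest
  expect_identical(d$n0[1:7], c(25, 50, 100, 250, 500, 750, 1000))
  expect_identical(d$travel_time[1:8], c(rep(100, 7), 200))
  d2 <- full_design(design_grid(n0 = c(25, 1000), travel_time = c(100, 500),
                                p_natal = c(0, 1), cost = c(0.1, 0.5)))
  expect_identical(nrow(d2), 16L)
  d1 <- full_design(design_grid(n0 = 100, travel_time = 300, p_natal = 0.5,
                                cost = 0.2))
  expect_identical(nrow(d1), 1L)
  expect_error(design_grid(n0 = numeric(0)), "at least one level")
})

test_that("the 4-way ANOVA with two-way interactions has the study's df structure", {
  res <- placeholder_results()
  tab <- anova_table(res, "g1_opt")
  df <- setNames(tab$df, tab$effect)
  expect_identical(df[["patch_quality"]], 6L)
  expect_identical(df[["travel_time"]], 4L)
  expect_identical(df[["p_natal"]], 4L)
  expect_identical(df[["cost"]], 4L)
  expect_identical(df[["patch_quality:travel_time"]], 24L)
  expect_identical(df[["patch_quality:p_natal"]], 24L)
  expect_identical(df[["patch_quality:cost"]], 24L)
  expect_identical(df[["travel_time:p_natal"]], 16L)
  expect_identical(df[["travel_time:cost"]], 16L)
  expect_identical(df[["p_natal:cost"]], 16L)
  expect_identical(df[["residual"]], 736L)
  expect_identical(sum(tab$df), 875L - 1L)
})

test_that("ANOVA df arithmetic holds on a reduced balanced grid", {
  res <- placeholder_results(design_grid(n0 = c(25, 1000),
                                         travel_time = c(100, 500),
                                         p_natal = c(0, 1),
                                         cost = c(0.1, 0.5)))
  tab <- anova_table(res, "g2_opt")
  expect_identical(tab$df[tab$effect == "residual"], 5L)
  expect_identical(sum(tab$df), 15L)
})

test_that("incomplete or duplicated results tables are rejected by name", {
  res <- placeholder_results(design_grid(n0 = c(25, 100),
                                         travel_time = c(100, 300),
                                         p_natal = c(0, 1),
                                         cost = c(0.1, 0.5)))
  expect_error(anova_table(res[-3, ], "g1_opt"), "missing cells")
  expect_error(anova_table(rbind(res, res[1, ]), "g1_opt"), "duplicated")
  expect_error(anova_table(res, "nope"), "unknown response")
})

test_that("trend summaries report per-level means and standard errors", {
  res <- placeholder_results(design_grid(n0 = c(25, 100),
                                         travel_time = c(100, 300),
                                         p_natal = c(0, 1),
                                         cost = c(0.1, 0.5)))
  res$const <- 7
  ts <- trend_summary(res, "travel_time", "const")
  expect_identical(ts$mean, c(7, 7))
  expect_identical(ts$se, c(0, 0))
  ts2 <- trend_summary(res, "n0", "g1_opt")
  expect_identical(ts2$n, c(8L, 8L))
  expect_equal(ts2$mean[1], mean(res$g1_opt[res$n0 == 25]))
  # single-cell level: SE is undefined
  one <- res[res$n0 == 25 & res$travel_time == 100 &
               res$p_natal == 0 & res$cost == 0.1, ]
  expect_true(is.na(trend_summary(one, "n0", "g1_opt")$se))
  expect_error(trend_summary(res, "bogus", "g1_opt"), "unknown factor")
})

test_that("per-cell seeds are deterministic, distinct and within 32-bit range", {
  s <- vapply(1:875, function(i) cell_seed(42, i), integer(1))
  expect_identical(s, vapply(1:875, function(i) cell_seed(42, i), integer(1)))
  expect_identical(anyDuplicated(s), 0L)
  expect_true(all(s >= 1 & s < 2^31))
  expect_false(any(vapply(1:875, function(i) cell_seed(43, i), integer(1))
                   == s))
})

test_that("run_design optimizes every cell reproducibly", {
  ctrl <- ga_control(pop_size = 12, cycles = 20, restarts = 1,
                     fitness_generations = 5)
  d1 <- full_design(design_grid(n0 = 100, travel_time = 300, p_natal = 0.5,
                                cost = 0.2))
  r1 <- run_design(d1, ctrl, master_seed = 7, quiet = TRUE)
  expect_identical(nrow(r1), 1L)
  d <- full_design(design_grid(n0 = c(25, 1000), travel_time = c(100, 500),
                               p_natal = 0.5, cost = 0.3))
  ra <- run_design(d, ctrl, master_seed = 7, quiet = TRUE)
  rb <- run_design(d, ctrl, master_seed = 7, quiet = TRUE)
  expect_identical(ra, rb)
  expect_true(all(ra$g1_opt >= 0 & ra$g1_opt <= 1000))
  expect_true(all(ra$g2_opt >= 0 & ra$g2_opt <= 1000))
  expect_true(all(ra$g3_opt >= 0 & ra$g3_opt <= 1))
  expect_identical(ra$seed, vapply(ra$cell, function(i) cell_seed(7, i),
                                   integer(1)))
})

test_that("run_design resumes from an existing output file", {
  ctrl <- ga_control(pop_size = 12, cycles = 20, restarts = 1,
                     fitness_generations = 5)
  d <- full_design(design_grid(n0 = c(25, 1000), travel_time = 100,
                               p_natal = 1, cost = 0.3))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  full <- run_design(d, ctrl, master_seed = 3, out_file = f, quiet = TRUE)
  # rewrite only the first cell, then resume: the second must be reused
  utils::write.csv(full[1, ], f, row.names = FALSE)
  resumed <- suppressMessages(
    run_design(d, ctrl, master_seed = 3, out_file = f, quiet = FALSE))
  expect_equal(resumed$g1_opt, full$g1_opt)
  expect_equal(resumed$best_fitness, full$best_fitness)
})
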