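test_that("cognitive classification follows the z/MMSE rules exactly", {
  expect_equal(classify_cognitive_status(c(0, 0, 0, 0, 0), 28), "PDN")
  expect_equal(classify_cognitive_status(c(-2, -2, 0, 0, 0), 27), "PD-MCI")
  expect_equal(classify_cognitive_status(c(-2, -2, 0, 0, 0), 25), "PDD")
  # boundary: z = -1.5 counts as impaired; MMSE = 26 is not demented
  expect_equal(classify_cognitive_status(c(-1.5, -1.5, 0, 0, 0), 26),
               "PD-MCI")
  expect_equal(classify_cognitive_status(c(-1.49, -1.5, 0, 0, 0), 20),
               "PDN")   # single impaired domain stays PDN even with low MMSE
  expect_equal(classify_cognitive_status(c(-2, -2, -2, -2, -2), 25.9),
               "PDD")
  # vectorised over subjects
  z <- rbind(c(0, 0, 0, 0, 0), c(-2, -2, 0, 0, 0), c(-2, -2, 0, 0, 0))
  expect_equal(classify_cognitive_status(z, c(30, 27, 20)),
               c("PDN", "PD-MCI", "PDD"))
  expect_error(classify_cognitive_status(c(0, 0, NA, 0, 0), 25),
               class = "alps_validation_error")
})

test_that("HY split is boundary-inclusive at stage 2", {
  co <- toy_cohort()
  co$hy[co$group != "NC"] <- c(2, 2.5, 0, rep(3, sum(co$group != "NC") - 3))
  out <- hy_split(co)
  pd <- out[out$group != "NC", ]
  expect_equal(pd$hy_stage_group[1:3], c("early", "late", "early"))
  expect_true(all(is.na(out$hy_stage_group[out$group == "NC"])))
  co$hy[co$group == "PDD"][1] <- NA
  expect_error(hy_split(co), class = "alps_validation_error")
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  df <- data.frame(y = c(1, 2, 3, 4, 5, 6),
                   g = rep(c("a", "b"), each = 3))
  res <- anova_oneway(df, "y", "g")
  expect_equal(res$statistic, 13.5)        # SSB = 13.5, MSW = 1
  expect_equal(res$df, "1, 4")
  ora <- oracle_anova_F(df$y, df$g)
  expect_equal(res$p, ora$p, tolerance = 1e-12)

  # identical groups: F = 0, p = 1
  same <- data.frame(y = rep(1, 8), g = rep(c("a", "b"), each = 4))
  res0 <- anova_oneway(same, "y", "g")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  withr::local_seed(8)
  for (rep in 1:10) {
    d <- data.frame(y = rnorm(30), g = sample(letters[1:3], 30, TRUE))
    got <- anova_oneway(d, "y", "g")
    ora <- oracle_anova_F(d$y, d$g)
    expect_equal(got$statistic, ora$F, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
  }
})

test_that("chi-square matches the expected-count oracle and handles nulls", {
  res <- chi_square_independence(rbind(c(10, 10), c(10, 10)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  withr::local_seed(9)
  for (rep in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    got <- chi_square_independence(tab)
    ora <- oracle_chisq(tab)
    expect_equal(got$statistic, ora$X2, tolerance = 1e-12)
    expect_equal(got$p, ora$p, tolerance = 1e-12)
  }
  expect_error(chi_square_independence(rbind(c(0, 0), c(5, 5))),
               class = "alps_validation_error")
})

test_that("ANCOVA group F matches the two-model RSS oracle", {
  df <- ancova_fixture()
  fit <- ancova(df, "y", covariates = c("age", "sex"))
  ora <- oracle_ancova_F(df$y, df$group, df$age, df$sex)
  expect_equal(fit$statistic, ora$F, tolerance = 1e-10)
  expect_equal(fit$p, ora$p, tolerance = 1e-10)
  expect_equal(c(fit$df1, fit$df2), c(ora$df1, ora$df2))
  expect_equal(nrow(tidy(fit)), 3)   # adjusted mean per group
  expect_equal(glance(fit)$nobs, 12)
})

test_that("constant covariates reduce ANCOVA to one-way ANOVA", {
  df <- ancova_fixture()
  df$age <- 65
  df$sex <- "F"
  fit <- suppressMessages(ancova(df, "y"))
  res <- anova_oneway(df, "y", "group")
  expect_equal(fit$statistic, res$statistic, tolerance = 1e-10)
  expect_equal(fit$p, res$p, tolerance = 1e-10)
})

test_that("Bonferroni post hoc is a capped monotone transform", {
  df <- ancova_fixture()
  ph <- bonferroni_posthoc(ancova(df, "y"))
  expect_equal(nrow(ph), 3)           # 3 groups -> 3 pairs
  expect_equal(ph$p_adj, pmin(1, 3 * ph$p))
  expect_true(all(ph$p_adj >= ph$p))
  expect_equal(order(ph$p), order(ph$p_adj))

  co <- toy_cohort(n_per_group = 5)
  ph4 <- bonferroni_posthoc(suppressMessages(ancova(co, "alps")))
  expect_equal(nrow(ph4), 6)          # 4 groups -> 6 pairs
  expect_equal(ph4$p_adj, pmin(1, 6 * ph4$p))
})

test_that("Spearman rho matches the average-rank oracle, ties included", {
  d <- data.frame(x = c(1, 2, 3), y = c(10, 20, 30))
  expect_equal(spearman_cor(d, "x", "y")$statistic, 1)
  d$y <- rev(d$y)
  expect_equal(spearman_cor(d, "x", "y")$statistic, -1)

  dt <- data.frame(x = c(1, 2, 2, 4), y = c(1, 3, 2, 4))
  got <- spearman_cor(dt, "x", "y")
  expect_equal(got$statistic, oracle_spearman_rho(dt$x, dt$y),
               tolerance = 1e-12)

  withr::local_seed(10)
  for (rep in 1:10) {
    d <- data.frame(x = sample(1:5, 12, TRUE), y = rnorm(12))
    expect_equal(spearman_cor(d, "x", "y")$statistic,
                 oracle_spearman_rho(d$x, d$y), tolerance = 1e-12)
  }
  expect_error(spearman_cor(data.frame(x = c(1, 1, 1), y = 1:3), "x", "y"),
               class = "alps_validation_error")
})

test_that("t-approximate Spearman p agrees with the exact permutation null", {
  withr::local_seed(12)
  d <- data.frame(x = rnorm(7), y = rnorm(7))
  approx_p <- spearman_cor(d, "x", "y")$p
  exact_p <- spearman_cor(d, "x", "y", exact = TRUE)$p
  expect_lt(abs(approx_p - exact_p), 0.12)
  # the exact mode is a genuine permutation tail probability
  expect_true(exact_p >= 0 && exact_p <= 1)
  expect_error(spearman_cor(data.frame(x = rnorm(12), y = rnorm(12)),
                            "x", "y", exact = TRUE),
               class = "alps_validation_error")
})

test_that("the full battery runs and reports every family", {
  co <- toy_cohort(n_per_group = 8)
  ga <- suppressMessages(run_group_analysis(co))
  td <- tidy(ga)
  expect_true(all(c("anova", "chi_square", "ancova", "ancova_posthoc",
                    "spearman") %in% td$test))
  expect_true(all(td$p >= 0 & td$p <= 1, na.rm = TRUE))
  expect_true(all(td$p_adj >= td$p, na.rm = TRUE))
  # 7 correlation rows: 4 across all subjects, 3 within PD
  expect_equal(nrow(ga$correlations), 7)
  expect_equal(glance(ga)$n_subjects, nrow(co))

  # missing rows are dropped per test with a message, not an error
  co$nuclear_dna[1] <- NA
  msgs <- capture_messages(run_group_analysis(co))
  expect_true(any(grepl("dropped", msgs)))
})

test_that("missing-variable rows are dropped only from affected tests", {
  co <- toy_cohort(n_per_group = 6)
  co$mmse[1:2] <- NA
  suppressMessages({
    ga <- run_group_analysis(co)
  })
  mmse_row <- ga$ancova[ga$ancova$variable == "mmse", ]
  alps_row <- ga$ancova[ga$ancova$variable == "alps", ]
  df2 <- function(r) as.numeric(sub(".*, ", "", r$df))
  expect_equal(df2(mmse_row), df2(alps_row) - 2)
})
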