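# KS normality screen, two-way ANOVA, post-hoc comparisons, calibration.

test_that("KS screen accepts normal and rejects heavy-tailed samples", {
  set.seed(101)
  normal <- rnorm(1000)
  res <- ks_normality(normal)
  expect_gt(res$p_value, 0.05)
  expect_match(res$caveat, "estimated")

  set.seed(102)
  heavy <- rcauchy(1000)
  expect_lt(ks_normality(heavy)$p_value, 0.05)

  expect_error(ks_normality(rep(3, 10)), "zero variance")
  expect_error(ks_normality(1:3), "n >= 5")
})

test_that("ANOVA SS decomposition matches brute-force arithmetic exactly", {
  # hand-computable 2x2 design with 2 replicates: 1,2 | 3,4 | 5,6 | 7,8
  df <- data.frame(
    speed = rep(c("a1", "a2"), each = 4),
    load = rep(rep(c("b1", "b2"), each = 2), 2),
    value = c(1, 2, 3, 4, 5, 6, 7, 8)
  )
  an <- two_way_anova(df, "value")
  expect_equal(an$ss, c(32, 8, 0, 2, 42))
  expect_equal(an$df, c(1, 1, 1, 4, 7))
  oracle <- brute_force_anova(df, "value", "speed", "load")
  expect_equal(an$ss, unname(oracle))

  # random balanced design: brute force and aov both agree
  df2 <- null_grid_df(4, speeds = 1:3, loads = 1:4, seed = 5,
                      effect = function(s, l) 0.3 * s + 0.1 * l)
  an2 <- two_way_anova(df2, "value")
  oracle2 <- brute_force_anova(df2, "value", "speed", "load")
  expect_equal(an2$ss, unname(oracle2), tolerance = 1e-12)
  fit <- stats::aov(value ~ factor(speed) * factor(load), data = df2)
  ref <- summary(fit)[[1]]
  expect_equal(an2$ss[1:4], ref[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(an2$p[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
})

test_that("ANOVA enforces its invariants and degenerate rules", {
  df <- null_grid_df(5, speeds = 1:7, loads = 1:7, seed = 9)
  an <- two_way_anova(df, "value")
  # SS conservation and the balanced-design degrees of freedom
  expect_equal(sum(an$ss[1:4]), an$ss[5], tolerance = 1e-9)
  expect_equal(an$df[1:4], c(6, 6, 36, 7 * 7 * (5 - 1)))
  expect_true(all(an$p[1:3] >= 0 & an$p[1:3] <= 1))

  # identical cells: everything zero, test undefined
  const <- df
  const$value <- 2.5
  an0 <- two_way_anova(const, "value")
  expect_equal(an0$ss, rep(0, 5))
  expect_true(all(is.na(an0$f[1:3])))

  expect_error(two_way_anova(df[-1, ], "value"), "unbalanced")
  one_rep <- df[!duplicated(df[c("speed", "load")]), ]
  expect_error(two_way_anova(one_rep, "value"), ">= 2 replicates")
})

test_that("post-hoc comparisons behave and match TukeyHSD", {
  df <- null_grid_df(6, speeds = 1:7, loads = 1:3, seed = 13)
  mc <- multiple_comparisons(df, "value", "speed", other = "load")
  expect_equal(nrow(mc), choose(7, 2))
  expect_true(all(mc$p_adj >= mc$p_raw))

  fit <- stats::aov(value ~ factor(speed) * factor(load), data = df)
  ref <- stats::TukeyHSD(fit, "factor(speed)")[[1]]
  key <- paste(mc$level_2, mc$level_1, sep = "-")
  expect_equal(mc$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-8)
  expect_equal(mc$diff, unname(ref[key, "diff"]), tolerance = 1e-12)

  # identical marginal means: nothing significant
  const <- df
  const$value <- 1
  mc0 <- multiple_comparisons(const, "value", "speed", other = "load")
  expect_true(all(!mc0$significant | is.na(mc0$significant)))

  # one level shifted by 10 residual SDs: all its pairs flagged
  shifted <- df
  shifted$value[shifted$speed == 4] <- shifted$value[shifted$speed == 4] + 10
  mc1 <- multiple_comparisons(shifted, "value", "speed", other = "load")
  involving4 <- mc1$level_1 == "4" | mc1$level_2 == "4"
  expect_true(all(mc1$significant[involving4]))

  expect_error(multiple_comparisons(df[df$speed == 1, ], "value", "speed",
                                    other = "load"), ">= 2 levels")

  # bonferroni adjusts by the number of pairs
  mcb <- multiple_comparisons(df, "value", "speed", other = "load",
                              method = "bonferroni")
  expect_equal(mcb$p_adj, pmin(1, mcb$p_raw * nrow(mcb)))
})

test_that("type-I error is calibrated and additive effects leave no interaction", {
  rates <- calibrate_anova_type1(n_sims = 300, n_subjects = 8,
                                 n_a = 4, n_b = 4, seed = 2024)
  band <- 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(rates[["a"]] - 0.05), band)
  expect_lt(abs(rates[["b"]] - 0.05), band)
  expect_lt(abs(rates[["ab"]] - 0.05), band)

  # purely additive speed and load effects keep the interaction at alpha
  set.seed(77)
  hits <- 0L
  n_sims <- 200
  for (i in seq_len(n_sims)) {
    df <- null_grid_df(5, speeds = 1:7, loads = 1:7, seed = 77 + i,
                       effect = function(s, l) 0.2 * s + 0.1 * l)
    an <- two_way_anova(df, "value")
    hits <- hits + (an$p[an$source == "interaction"] < 0.05)
  }
  expect_lt(abs(hits / n_sims - 0.05), 1.96 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("a load effect of the published ankle size is reliably detected", {
  # peak ankle torque rises about 34% from 0 to 20 kg (1.18 -> 1.59 Nm/kg
  # at 1 km/h) against a between-subject SD near 0.22; at n = 15 the load
  # main effect should be detected in > 90% of simulated grids
  loads <- default_loads()
  load_effect <- 1.18 * 0.34 * loads / 20
  detected <- 0L
  n_sims <- 100
  for (i in seq_len(n_sims)) {
    set.seed(500 + i)
    cells <- expand.grid(subject = 1:15, speed = 1:7, load = loads)
    subj_offset <- rnorm(15, 0, 0.22)
    cells$value <- 1.18 + load_effect[match(cells$load, loads)] +
      subj_offset[cells$subject] + rnorm(nrow(cells), 0, 0.05)
    an <- two_way_anova(cells, "value")
    detected <- detected + an$significant[an$source == "load"]
  }
  expect_gt(detected / n_sims, 0.9)
})
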