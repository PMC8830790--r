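# Frozen oracle values computed independently with scipy.stats.normaltest
# (D'Agostino-Pearson omnibus) on the literal samples below.
oracle_a <- c(7.741917, 3.870604, 5.726257, 6.265725, 5.808537, 4.787751,
              8.023044, 4.810682, 9.036847, 4.874572, 7.609739, 9.573291,
              2.222279, 4.442422, 4.733357, 6.271901, 4.431494, -0.312911,
              0.119066, 7.640227)
oracle_b <- c(0.735917, 0.168418, 0.842049, 3.369198, 6.653836, 0.650204,
              0.77316, 0.171502, 1.584228, 0.527295, 1.576883, 2.023518,
              2.815398, 0.543935, 1.656911)
oracle_d <- c(-1.717009, -0.784459, -0.850908, -2.414208, 0.036123,
              0.205999, -0.361057, 0.758163)

test_that("D'Agostino-Pearson omnibus matches the independent oracle", {
  ra <- dagostino_pearson(oracle_a)
  expect_equal(ra$statistic, 1.8633630788, tolerance = 1e-9)
  expect_equal(ra$p_value, 0.3938908103, tolerance = 1e-9)
  rb <- dagostino_pearson(oracle_b)
  expect_equal(rb$statistic, 18.6191186321, tolerance = 1e-9)
  expect_equal(rb$p_value, 9.05544422722358e-05, tolerance = 1e-9)
  rd <- dagostino_pearson(oracle_d)
  expect_equal(rd$statistic, 0.5182455084, tolerance = 1e-9)
  expect_error(dagostino_pearson(1:5), "n >= 8")
  expect_error(dagostino_pearson(rep(2, 20)), "zero-variance")
})

test_that("normality_check branches on every group jointly", {
  expect_true(isTRUE(normality_check(list(oracle_a, oracle_d))))
  expect_false(isTRUE(normality_check(list(oracle_a, oracle_b))))
  expect_false(isTRUE(normality_check(list(oracle_a, rep(1, 10)))))
  expect_error(normality_check(list(c(1, 2))), "n >= 3")
  # n = 8 is the omnibus test's lower limit; below it Shapiro-Wilk runs
  tests <- attr(normality_check(list(oracle_a, oracle_d[1:7])), "tests")
  expect_equal(tests$test, c("dagostino_pearson", "shapiro_wilk"))
})

test_that("normality_check accepts normal and rejects lognormal samples", {
  set.seed(7)
  ok <- 0
  bad <- 0
  for (i in 1:100) {
    gs <- replicate(3, rnorm(30), simplify = FALSE)
    if (isTRUE(normality_check(gs))) ok <- ok + 1
    gs[[2]] <- exp(rnorm(30))
    if (!isTRUE(normality_check(gs))) bad <- bad + 1
  }
  expect_gte(ok, 70)   # joint pass rate ~ (1 - alpha)^3 under the null
  expect_gte(bad, 90)  # lognormal group detected
})

test_that("star_annotation follows the strict figure-legend thresholds", {
  expect_equal(star_annotation(c(0.02, 0.05, 5e-5)), c("*", "ns", "****"))
  expect_equal(star_annotation(c(0.0001, 0.001, 0.01)),
               c("***", "**", "*"))
  expect_equal(star_annotation(0.9), "ns")
  expect_error(star_annotation(-0.1), "\\[0, 1\\]")
  expect_error(star_annotation(1.2), "\\[0, 1\\]")
  # monotone: smaller p never yields fewer stars
  ps <- sort(c(10^runif(50, -6, 0)))
  rank_of <- c("ns" = 0, "*" = 1, "**" = 2, "***" = 3, "****" = 4)
  expect_true(all(diff(rank_of[star_annotation(ps)]) <= 0))
})

test_that("compare_two picks the branch and computes two-tailed p", {
  set.seed(13)
  x <- rnorm(10)
  same <- compare_two(x, x)
  expect_equal(same$branch, "parametric")
  expect_equal(same$p, 1)

  set.seed(11)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 3, 1)
  big <- compare_two(a, b)
  expect_lt(big$p, 0.0001)
  expect_equal(big$stars, "****")

  set.seed(17)
  l1 <- exp(rnorm(20, 0, 1.5))
  l2 <- exp(rnorm(20, 1, 1.5))
  ln <- compare_two(l1, l2)
  expect_equal(ln$branch, "nonparametric")
  expect_equal(ln$test, "Mann-Whitney")

  expect_error(compare_two(c(1, 2), c(1, 2, 3)), "n >= 3")
  expect_error(compare_two(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("compare_many_vs_control runs ANOVA-Dunnett or KW-Dunn", {
  set.seed(19)
  groups <- list(control = rnorm(20), g1 = rnorm(20), g2 = rnorm(20, 5))
  res <- compare_many_vs_control(groups, "control")
  expect_equal(nrow(res), 2)
  expect_equal(res$branch, rep("parametric", 2))
  expect_true(all(res$adjusted))
  big <- res[res$comparison == "g2 vs control", ]
  expect_equal(big$stars, "****")
  # deterministic despite the multivariate-t machinery
  res2 <- compare_many_vs_control(groups, "control")
  expect_identical(res$p, res2$p)

  set.seed(23)
  skewed <- list(control = exp(rnorm(20, 0, 1.5)),
                 g1 = exp(rnorm(20, 0, 1.5)),
                 g2 = exp(rnorm(20, 2, 1.5)))
  resk <- compare_many_vs_control(skewed, "control")
  expect_equal(resk$branch, rep("nonparametric", 2))
  expect_equal(resk$test, rep("Kruskal-Wallis + Dunn", 2))

  expect_error(compare_many_vs_control(groups[1:2], "control"),
               "at least 3")
  expect_error(compare_many_vs_control(groups, "nope"), "control label")
})

test_that("Dunn vs-control z and Bonferroni p match the rank oracle", {
  # hand-checked fixture (ties across groups): frozen from an independent
  # rank computation
  g <- list(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
            c = c(10, 11, 12, 9, 13))
  res <- olfint:::dunn_vs_control(unlist(g), rep(c("a", "b", "c"), each = 5),
                                  "a")
  expect_equal(res$statistic, c(1.1698639612, 3.0841868067),
               tolerance = 1e-9)
  expect_equal(res$p, c(0.4841114378, 0.0040821878), tolerance = 1e-9)
})

test_that("family-wise error of many-vs-control under the null is controlled", {
  set.seed(29)
  any_sig <- 0
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    groups <- list(control = rnorm(20), g1 = rnorm(20), g2 = rnorm(20))
    res <- compare_many_vs_control(groups, "control")
    if (any(res$p < 0.05)) any_sig <- any_sig + 1
  }
  expect_lte(any_sig / n_rep, 0.08)
})
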