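test_that("identical groups give F = 0 and p = 1", {
  df <- tibble::tibble(dsc = rep(c(1, 2, 3), 2),
                       arm = rep(c("a", "b"), each = 3))
  an <- one_way_anova(df)
  expect_equal(an$statistic, 0)
  expect_equal(an$p_value, 1)
  expect_identical(an$df, c(1, 4))
  td <- tidy(an)
  expect_identical(colnames(td),
                   c("df_between", "df_within", "statistic", "p_value"))
  expect_equal(glance(an)$statistic, 0)
})

test_that("F grows monotonically with a group shift", {
  base <- c(0.1, 0.2, 0.3, 0.4)
  fs <- vapply(c(0.1, 0.3, 0.6, 1.2), function(sh) {
    df <- tibble::tibble(dsc = c(base, base + sh),
                         arm = rep(c("a", "b"), each = 4))
    one_way_anova(df)$statistic
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("ANOVA agrees with the textbook sums-of-squares oracle", {
  set.seed(10)
  for (i in 1:5) {
    df <- tibble::tibble(
      dsc = c(rnorm(7, 0.6, 0.1), rnorm(9, 0.7, 0.12), rnorm(8, 0.65, 0.1)),
      arm = rep(c("manual", "model1", "model2"), c(7, 9, 8)))
    an <- one_way_anova(df)
    or <- oracle_anova(df$dsc, df$arm)
    expect_equal(an$statistic, or$f, tolerance = 1e-10)
    expect_equal(an$p_value, or$p, tolerance = 1e-10)
    expect_gte(an$statistic, 0)
    expect_gt(an$p_value, 0); expect_lte(an$p_value, 1)
  }
  expect_error(one_way_anova(tibble::tibble(dsc = 1:3,
                                            arm = c("a", "a", "b"))),
               "at least two values")
})

test_that("Tukey HSD agrees with the studentized-range oracle", {
  set.seed(11)
  for (i in 1:5) {
    df <- tibble::tibble(
      dsc = c(rnorm(6, 0.5, 0.1), rnorm(8, 0.62, 0.1), rnorm(7, 0.7, 0.08)),
      arm = rep(c("a", "b", "c"), c(6, 8, 7)))
    tk <- tukey_hsd(df)
    expect_identical(nrow(tk$table), 3L)
    orc <- oracle_tukey(df$dsc, df$arm)
    for (row in seq_len(3))
      expect_equal(tk$table$p_adj[row], unname(orc[tk$table$pair[row]]),
                   tolerance = 1e-6)
  }
})

test_that("Tukey rejects exactly the pairs involving an outlying group", {
  set.seed(12)
  g <- rnorm(8, 0.8, 0.02)
  df <- tibble::tibble(dsc = c(g, g + rnorm(8, 0, 0.01), g - 10),
                       arm = rep(c("a", "b", "out"), each = 8))
  tk <- tukey_hsd(df)
  rej <- tk$table$reject[order(tk$table$pair)]
  names(rej) <- sort(tk$table$pair)
  expect_false(rej[["b-a"]])
  expect_true(rej[["out-a"]])
  expect_true(rej[["out-b"]])
  # identical groups: nothing rejected
  df2 <- tibble::tibble(dsc = rep(c(1, 2, 3), 3),
                        arm = rep(c("a", "b", "c"), each = 3))
  expect_false(any(tukey_hsd(df2)$table$reject))
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise tests", {
  set.seed(13)
  df <- tibble::tibble(
    dsc = c(rnorm(8, 0.6, 0.1), rnorm(8, 0.66, 0.1), rnorm(8, 0.72, 0.1)),
    arm = rep(c("a", "b", "c"), each = 8))
  tk <- tukey_hsd(df)
  # unadjusted pairwise p from the same pooled within-group variance
  msw <- sum(tapply(df$dsc, df$arm, function(v) sum((v - mean(v))^2))) /
    (nrow(df) - 3)
  for (row in seq_len(nrow(tk$table))) {
    se <- sqrt(msw * (1 / 8 + 1 / 8))
    p_unadj <- 2 * stats::pt(-abs(tk$table$diff[row]) / se, nrow(df) - 3)
    expect_gte(tk$table$p_adj[row], p_unadj - 1e-12)
  }
})

test_that("score summaries use the fixed quantile rule", {
  df <- tibble::tibble(dsc = c(0.2, 0.5, 0.8))
  sm <- summarize_scores(df)
  expect_equal(sm$median, 0.5)
  expect_equal(c(sm$min, sm$max), c(0.2, 0.8))
  one <- summarize_scores(tibble::tibble(dsc = 0.42))
  expect_true(all(one[c("median", "min", "max", "q1", "q3")] == 0.42))

  set.seed(14)
  v <- runif(100)
  sm2 <- summarize_scores(tibble::tibble(dsc = v))
  # sort-based linear interpolation oracle for the quartiles
  sv <- sort(v)
  qq <- function(p) {
    h <- (100 - 1) * p + 1
    lo <- floor(h)
    sv[lo] + (h - lo) * (sv[lo + 1] - sv[lo])
  }
  expect_equal(sm2$q1, qq(0.25), tolerance = 1e-12)
  expect_equal(sm2$q3, qq(0.75), tolerance = 1e-12)
  expect_equal(sm2$median, qq(0.5), tolerance = 1e-12)
  # permutation invariance
  sm3 <- summarize_scores(tibble::tibble(dsc = sample(v)))
  expect_equal(sm2, sm3)
  expect_error(summarize_scores(tibble::tibble(dsc = NA_real_)), "scores")
})

test_that("grouped summaries produce one row per group", {
  df <- tibble::tibble(dsc = runif(20),
                       arm = rep(c("a", "b"), 10),
                       test_set = rep(c("x", "y"), each = 10))
  sm <- summarize_scores(df, by = c("test_set", "arm"))
  expect_identical(nrow(sm), 4L)
  expect_true(all(c("test_set", "arm", "median") %in% colnames(sm)))
})
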