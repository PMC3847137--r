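test_that("test selection follows normality and arity", {
  # under true normality the parametric branch is chosen at roughly the
  # Shapiro-Wilk pass rate (>= 90% over replicates)
  set.seed(51)
  picks <- replicate(100, choose_test(list(rnorm(50), rnorm(50, 1))))
  expect_gte(mean(picks == "t"), 0.9)

  set.seed(52)
  expect_equal(choose_test(list(rexp(200), rexp(200))), "mann-whitney")
  set.seed(53)
  expect_equal(choose_test(list(rnorm(40), rnorm(40), rnorm(40), rnorm(40))),
               "anova")
  set.seed(54)
  expect_equal(choose_test(list(rexp(200), rexp(200), rexp(200))), "kruskal")
  expect_error(choose_test(list(c(1, 2), c(1, 2, 3))), "n >= 3")
  expect_error(choose_test(list(rnorm(5))), "two groups")
})

test_that("group comparisons report the right statistics", {
  d <- data.frame(v = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  # identical groups: rank test p = 1, t statistic 0
  r_rank <- compare_groups(d, "v", "g", test = "mann-whitney")
  expect_equal(r_rank$p_value, 1)
  r_t <- compare_groups(d, "v", "g", test = "t")
  expect_equal(unname(r_t$statistic), 0)

  # widely separated groups: |t| = 100 / sqrt(2/3) = 122.47, p < 0.001
  d2 <- data.frame(v = c(1, 2, 3, 101, 102, 103), g = rep(c("a", "b"), each = 3))
  r2 <- compare_groups(d2, "v", "g", test = "t")
  expect_equal(unname(r2$statistic), -100 / sqrt(2 / 3), tolerance = 1e-10)
  expect_lt(r2$p_value, 0.001)

  # degenerate zero variance everywhere
  d3 <- data.frame(v = rep(5, 8), g = rep(c("a", "b"), each = 4))
  r3 <- compare_groups(d3, "v", "g", test = "anova")
  expect_true(is.na(r3$p_value))
  expect_match(r3$note, "degenerate")

  # summaries carry per-group n/mean/sd and the normality decision
  co <- simulate_cohort(cohort_spec(seed = 55))
  r4 <- compare_groups(co, "indexed_itfv")
  expect_equal(sum(r4$summaries$n), 110)
  expect_named(r4$summaries,
               c("group", "n", "mean", "sd", "median", "min", "max", "normal"))
  expect_true(r4$p_value >= 0 && r4$p_value <= 1)
})

test_that("group means reproduce the monotone cohort ordering at n = 200", {
  ok <- 0L
  for (seed in 1:25) {
    co <- simulate_cohort(cohort_spec(n = rep(400L, 4), seed = 500 + seed))
    m <- tapply(co$indexed_itfv, co$group, mean)
    if (all(diff(m) > 0)) ok <- ok + 1L
  }
  expect_gte(ok / 25, 0.95)
})

test_that("categorical test picks Fisher for small expected counts", {
  t1 <- categorical_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(t1$test, "chi-square")
  expect_equal(unname(t1$statistic), 0)
  expect_equal(t1$p_value, 1)

  t2 <- categorical_test(matrix(c(1, 8, 9, 2), 2))
  expect_equal(t2$test, "fisher")
  expect_true(any(t2$expected < 5))

  t3 <- categorical_test(matrix(c(50, 50, 50, 50), 2))
  expect_equal(t3$test, "chi-square")
  expect_equal(unname(t3$statistic), 0)

  expect_error(categorical_test(matrix(0, 2, 2)), "empty")
  expect_error(categorical_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("regression recovers exact linear structure and screens collinearity", {
  co <- simulate_cohort(cohort_spec(seed = 61))
  mi <- co[!is.na(co$scar_pct), ]
  mi$scar_exact <- 2 + 0.8 * mi$indexed_itfv
  fit <- suppressWarnings(  # summary.lm flags the perfect fit
    fit_infarct_regression(mi, outcome = "scar_exact",
                           predictors = "indexed_itfv"))
  expect_equal(fit$coefficients$estimate[2], 0.8, tolerance = 1e-10)
  expect_equal(fit$coefficients$estimate[1], 2, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # a duplicated predictor is excluded with r = 1
  mi$itfv_copy <- mi$indexed_itfv
  fit2 <- fit_infarct_regression(mi, predictors = c("indexed_itfv", "itfv_copy", "age"))
  expect_equal(fit2$included, c("indexed_itfv", "age"))
  expect_match(fit2$excluded$reason, "collinear with indexed_itfv")

  # the engineered waist-ITFV coupling trips the screen at |r| > 0.7
  fit3 <- fit_infarct_regression(mi, predictors = c("indexed_itfv", "waist_cm", "age"))
  expect_true("waist_cm" %in% fit3$excluded$predictor)

  # constant predictors are excluded as degenerate
  mi$flag <- TRUE
  fit4 <- fit_infarct_regression(mi, predictors = c("indexed_itfv", "flag"))
  expect_match(fit4$excluded$reason[1], "constant")

  expect_error(fit_infarct_regression(mi[1:3, ],
                                      predictors = c("indexed_itfv", "age", "bmi")),
               "n >")
  expect_error(fit_infarct_regression(mi, predictors = "nope"), "not found")
})

test_that("regression slope is recovered when the linear law generates the data", {
  # single positive intercept keeps the zero-truncation inactive, so the
  # fitted model matches the generating model
  slopes <- vapply(1:40, function(seed) {
    co <- simulate_cohort(cohort_spec(n = rep(60L, 4), scar_intercept = 30,
                                      seed = 700 + seed))
    mi <- co[!is.na(co$scar_pct), ]
    fit <- fit_infarct_regression(mi, predictors = c("indexed_itfv", "age", "gfr"))
    fit$coefficients$estimate[fit$coefficients$term == "indexed_itfv"]
  }, 1.0)
  expect_lt(abs(mean(slopes) - 0.8), 0.05 * 0.8)  # bias < 5% of the true slope
})

test_that("Bland-Altman agreement follows its closed form", {
  a <- c(10, 20, 30); b <- c(12, 18, 33)
  r <- bland_altman(a, b)
  expect_equal(r$bias, -1)
  expect_equal(r$sd_diff, sqrt(7), tolerance = 1e-12)  # 2.6458
  expect_equal(r$lower_limit, -1 - 1.96 * sqrt(7))
  expect_equal(r$upper_limit, -1 + 1.96 * sqrt(7))

  # identical pairs
  x <- c(5, 9, 14, 20)
  ri <- bland_altman(x, x)
  expect_equal(ri$bias, 0)
  expect_equal(ri$upper_limit - ri$lower_limit, 0)
  expect_equal(ri$pearson_r, 1)

  # constant offset: d = A - B = -c, zero-width limits
  rc <- bland_altman(x, x + 3)
  expect_equal(rc$bias, -3)
  expect_equal(rc$upper_limit - rc$lower_limit, 0)

  expect_error(bland_altman(1, 2), "2 pairs")

  # invariants on random pairs: limits bracket the bias, width is exactly
  # 2 * 1.96 * sd_diff
  set.seed(66)
  for (i in 1:10) {
    aa <- rnorm(12, 100, 20); bb <- aa + rnorm(12, 2, 5)
    rr <- bland_altman(aa, bb)
    expect_true(rr$lower_limit <= rr$bias && rr$bias <= rr$upper_limit)
    expect_equal(rr$upper_limit - rr$lower_limit, 2 * 1.96 * rr$sd_diff)
  }
})
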