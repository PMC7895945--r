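test_that("noise-free data recovers the exact slope; singular designs error", {
  set.seed(1)
  d <- data.frame(animal_id = rep(letters[1:5], each = 6), x = runif(30))
  off <- setNames(rnorm(5), letters[1:5])
  d$y <- 2 + 0.05 * d$x + off[d$animal_id]
  m <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(d, "y", "x")))
  expect_equal(m$coefficients$estimate[m$coefficients$term == "x"], 0.05,
               tolerance = 1e-8)
  expect_identical(m$method, "REML")
  expect_identical(m$n_groups, 5L)

  d$x2 <- 2 * d$x
  expect_error(fit_random_intercept_model(d, "y", c("x", "x2")),
               "collinear")

  d1 <- d[d$animal_id == "a", ]
  w <- capture_warnings(m1 <- fit_random_intercept_model(d1, "y", "x"))
  expect_true(any(grepl("single grouping level", w)))
  expect_identical(m1$method, "OLS-fallback")
})

test_that("marginal R2: limiting cases, designed ratio, affine invariance", {
  set.seed(2)
  # perfect fixed-effect fit, no random variance -> R2 ~ 1
  d <- data.frame(animal_id = rep(letters[1:4], each = 5), x = runif(20))
  d$y <- 1 + 3 * d$x
  m <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(d, "y", "x")))
  expect_gt(marginal_r2(m), 0.999)

  # no fixed effect at all -> R2 ~ 0
  d$y2 <- rep(rnorm(4, 0, 2), each = 5) + rnorm(20, 0, 0.5)
  m0 <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(d, "y2", "x")))
  expect_lt(marginal_r2(m0), 0.15)

  # variance components designed 1:1:2 -> R2 ~ 0.25 on average
  r2s <- vapply(1:60, function(s) {
    set.seed(s)
    dd <- data.frame(animal_id = rep(1:10, each = 8), x = rnorm(80))
    dd$y <- dd$x + rep(rnorm(10), each = 8) + rnorm(80, 0, sqrt(2))
    mm <- suppressWarnings(suppressMessages(
      fit_random_intercept_model(dd, "y", "x")))
    marginal_r2(mm)
  }, numeric(1))
  se <- sd(r2s) / sqrt(length(r2s))
  expect_lt(abs(mean(r2s) - 0.25), 2 * se + 0.02)

  # invariance under affine rescaling of the response
  dd <- simulate_long_table(0.3, seed = 7)
  ma <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(dd, "y", "x")))
  dd$y <- 100 * dd$y - 40
  mb <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(dd, "y", "x")))
  expect_equal(marginal_r2(ma), marginal_r2(mb), tolerance = 1e-6)
})

test_that("VIF closed form and collinearity error", {
  # construct predictors with empirical correlation exactly 0.9
  n <- 200
  x1 <- scale(rnorm(n))[, 1]
  e <- scale(resid(lm(rnorm(n) ~ x1)))[, 1]
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e
  v <- vif(data.frame(x1 = x1, x2 = x2), c("x1", "x2"))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-9)

  # orthogonal predictors -> VIF 1
  x3 <- scale(resid(lm(rnorm(n) ~ x1 + x2)))[, 1]
  v3 <- vif(data.frame(x1 = x1, x3 = x3), c("x1", "x3"))
  expect_equal(unname(v3), c(1, 1), tolerance = 1e-9)

  suppressWarnings(
    expect_error(vif(data.frame(a = x1, b = 2 * x1), c("a", "b")),
                 "collinearity"))
})

test_that("pairwise timepoint contrasts with Holm / Tukey corrections", {
  set.seed(4)
  d <- data.frame(animal_id = rep(letters[1:8], each = 3),
                  timepoint = rep(c(0, 1, 12), 8))
  d$y <- 100 + 2 * (d$timepoint == 12) +
    rep(rnorm(8, 0, 0.5), each = 3) + rnorm(24, 0, 0.5)
  m <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(d, "y", "timepoint")))
  ct <- pairwise_timepoint_contrasts(m)
  expect_identical(nrow(ct), 3L)
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-12))
  expect_true(all(ct$p_adj <= 1))
  big <- ct[ct$contrast %in% c("12 - 0", "12 - 1"), ]
  expect_true(all(big$estimate > 1))
  expect_true(all(big$p_adj < 0.05))

  tk <- pairwise_timepoint_contrasts(m, correction = "tukey")
  expect_true(all(tk$p_adj >= tk$p_raw - 1e-12))

  # two levels: the single contrast equals the model coefficient
  d2 <- d[d$timepoint != 12, ]
  m2 <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(d2, "y", "timepoint")))
  ct2 <- pairwise_timepoint_contrasts(m2)
  expect_identical(nrow(ct2), 1L)
  expect_equal(ct2$estimate,
               m2$coefficients$estimate[m2$coefficients$term == "timepoint"],
               tolerance = 1e-6)

  m1 <- m2
  m1$data <- m2$data[m2$data$timepoint == 0, ]
  expect_error(pairwise_timepoint_contrasts(m1), ">= 2 levels")
})

test_that("one-sample change test: Wilcoxon symmetry, errors, auto choice", {
  r <- one_sample_change_test(c(99, 101), method = "wilcoxon")
  expect_equal(r$p_value, 1)

  expect_error(one_sample_change_test(c(95, 95, 95), method = "t"),
               "zero variance")
  expect_error(one_sample_change_test(rep(100, 5), method = "wilcoxon"),
               "tie")

  set.seed(5)
  rn <- one_sample_change_test(rnorm(40, 100, 2))
  expect_identical(rn$method, "t")
  rsk <- one_sample_change_test(100 + rexp(40)^2)
  expect_identical(rsk$method, "wilcoxon")
})

test_that("t-test type-I error is calibrated (simulation)", {
  set.seed(6)
  rej <- mean(vapply(1:500, function(i) {
    one_sample_change_test(rnorm(20, 100, 3), method = "t")$p_value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("repeated-measures ANOVA with Tukey post hoc", {
  set.seed(7)
  d <- data.frame(animal_id = rep(1:10, each = 3),
                  timepoint = rep(c(0, 1, 12), 10))
  d$y <- 100 - 3 * (d$timepoint == 12) + rep(rnorm(10), each = 3) +
    rnorm(30, 0, 0.7)
  # one incomplete subject must be dropped silently
  d <- d[-(1:2), ]
  r <- repeated_measures_anova(d, "y", "timepoint", "animal_id")
  expect_lt(r$anova$p, 0.001)
  expect_identical(nrow(r$tukey), 3L)
  expect_true(all(r$tukey$p_adj >= 0 & r$tukey$p_adj <= 1))
  expect_lt(r$tukey$p_adj[r$tukey$contrast == "12 - 0"], 0.01)
})

test_that("model export writes valid JSON", {
  d <- simulate_long_table(0.5, seed = 8)
  d$x2 <- rnorm(nrow(d))
  m <- suppressWarnings(suppressMessages(
    fit_random_intercept_model(d, "y", c("x", "x2"))))
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$n_obs, m$n_obs)
  expect_equal(j$marginal_r2, m$marginal_r2, tolerance = 1e-9)
  expect_length(j$coefficients, 3)
  unlink(path)
})
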