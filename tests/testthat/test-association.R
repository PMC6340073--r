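test_that("2x2 risk ratio reproduces the log-scale Wald arithmetic", {
  # 4 infections among 6 exposed vs 14 among 49 unexposed
  e <- rr_from_2x2(4, 6, 14, 49)
  expect_equal(e$rr, (4 / 6) / (14 / 49))
  se <- sqrt(1 / 4 - 1 / 6 + 1 / 14 - 1 / 49)
  expect_equal(e$ci_low, exp(log(e$rr) - qnorm(0.975) * se))
  expect_equal(e$ci_high, exp(log(e$rr) + qnorm(0.975) * se))
  expect_equal(round(e$rr, 3), 2.333)
  expect_equal(round(c(e$ci_low, e$ci_high), 2), c(1.14, 4.79))

  # identical risks in both arms
  expect_equal(rr_from_2x2(5, 10, 10, 20)$rr, 1)
})

test_that("zero-cell tables error without, and resolve with, the correction", {
  expect_error(rr_from_2x2(0, 5, 3, 10), "correction")
  e <- rr_from_2x2(0, 5, 3, 10, correction = TRUE)
  expect_equal(e$rr, (0.5 / 6) / (3.5 / 11))
})

test_that("risk ratio is antisymmetric under arm swap", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(5:40, 1); n0 <- sample(5:40, 1)
    a <- sample(seq_len(n1 - 1), 1); c_ <- sample(seq_len(n0 - 1), 1)
    expect_equal(rr_from_2x2(a, n1, c_, n0)$rr *
                   rr_from_2x2(c_, n0, a, n1)$rr, 1)
  }
})

test_that("log-binomial single-binary fit equals the 2x2 closed form", {
  set.seed(31)
  reps <- 0L
  while (reps < 60L) {
    n1 <- sample(10:60, 1); n0 <- sample(10:60, 1)
    a <- sample(seq_len(n1 - 1), 1); c_ <- sample(seq_len(n0 - 1), 1)
    df <- data.frame(
      infected = c(rep(TRUE, a), rep(FALSE, n1 - a),
                   rep(TRUE, c_), rep(FALSE, n0 - c_)),
      x = rep(c(1, 0), c(n1, n0)))
    m <- fit_risk_model(infected ~ x, df, link = "log-binomial")
    expect_equal(m$estimates$rr, rr_from_2x2(a, n1, c_, n0)$rr,
                 tolerance = 1e-6)
    reps <- reps + 1L
  }
})

test_that("intercept-only log-likelihood equals the Bernoulli closed form", {
  df <- data.frame(infected = rep(c(TRUE, FALSE), c(18, 37)))
  m <- fit_risk_model(infected ~ 1, df, link = "logistic")
  p_hat <- 18 / 55
  expect_equal(m$loglik, 18 * log(p_hat) + 37 * log(1 - p_hat))
  expect_equal(m$aic, 2 * m$k - 2 * m$loglik)
})

test_that("coverage: CI covers the null effect near 95% for a null covariate", {
  set.seed(41)
  cover_rr <- cover_or <- 0L
  for (i in 1:200) {
    y <- runif(500) < 0.3
    # binary exposure, risk-ratio scale (log-binomial)
    df <- data.frame(infected = y, x = runif(500) < 0.4)
    m <- fit_risk_model(infected ~ x, df, link = "log-binomial")
    if (m$estimates$ci_low <= 1 && 1 <= m$estimates$ci_high)
      cover_rr <- cover_rr + 1L
    # continuous skewed covariate, odds scale (logistic)
    df2 <- data.frame(infected = y, x = rlnorm(500))
    m2 <- fit_risk_model(infected ~ x, df2, link = "logistic")
    if (m2$estimates$ci_low <= 1 && 1 <= m2$estimates$ci_high)
      cover_or <- cover_or + 1L
  }
  # binomial 99.9% band around 0.95 with 200 replicates
  lo <- 200 * 0.95 - 3.3 * sqrt(200 * 0.95 * 0.05)
  hi <- 200 * 0.95 + 3.3 * sqrt(200 * 0.95 * 0.05)
  expect_gt(cover_rr, lo); expect_lt(cover_rr, hi + 1)
  expect_gt(cover_or, lo); expect_lt(cover_or, hi + 1)
})

test_that("univariate screen ranks a strong risk feature first", {
  hits <- 0L
  for (s in 1:30) {
    coh <- generate_cohort(generator_config(
      n_patients = 1000, seed = s, effects = c(th17 = 2),
      binary_effects = c(cyclophosphamide = 0)))
    sc <- suppressWarnings(
      univariate_screen(coh, c("th17", "ldg", "lymphocytes")))
    if (sc$feature[1] == "th17" && sc$rr[1] > 1 && sc$p[1] < 0.05)
      hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.95)
})

test_that("constant features are skipped with a warning, not fatally", {
  df <- data.frame(infected = rep(c(TRUE, FALSE), 10),
                   flat = 1, ok = rnorm(20))
  expect_warning(sc <- univariate_screen(features = c("flat", "ok"),
                                         data = df), "flat")
  expect_equal(sc$feature, "ok")
})

test_that("AIC selection prefers the true predictor and breaks ties stably", {
  coh <- generate_cohort(strong_effects_config(n = 1000, seed = 3))
  tab <- baseline_table(coh)
  tab$noise <- rlnorm(nrow(tab))
  best <- select_model_by_aic(list("th17", "noise"), tab, link = "logistic")
  expect_equal(best$features, "th17")
  expect_equal(best$aic, 2 * best$k - 2 * best$loglik)

  # duplicate candidates: identical AIC, first by tie-break returned
  dup <- select_model_by_aic(list("th17", "th17"), tab, link = "logistic")
  expect_equal(dup$features, "th17")
  info <- attr(dup, "candidates")
  expect_equal(info$aic[1], info$aic[2])

  expect_error(select_model_by_aic(list("nope"), tab), "failed")
})

test_that("AIC ordering is invariant to affine recoding of covariates", {
  coh <- generate_cohort(strong_effects_config(n = 500, seed = 13))
  tab <- baseline_table(coh)
  m1 <- fit_risk_model(infected ~ th17, tab, link = "logistic")
  tab$th17s <- 100 + 5 * tab$th17
  m2 <- fit_risk_model(infected ~ th17s, tab, link = "logistic")
  expect_equal(m1$aic, m2$aic, tolerance = 1e-8)
})
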