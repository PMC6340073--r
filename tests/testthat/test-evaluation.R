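test_that("diagnostic metrics reproduce published-table arithmetic", {
  # 13 true positives, 0 false negatives, 2 false positives, 9 true negatives
  dm <- diagnostic_metrics(13, 0, 2, 9)
  expect_equal(dm$sens, 100)
  expect_equal(round(dm$sens_ci[["lower"]], 2), 75.29)
  expect_equal(round(dm$spec, 2), 81.82)
  expect_equal(round(dm$spec_ci[["lower"]], 2), 48.22)
  expect_equal(round(dm$spec_ci[["upper"]], 2), 97.72)
  expect_equal(dm$lr_pos, 5.5)
  expect_equal(dm$lr_neg, 0)

  perfect <- diagnostic_metrics(5, 0, 0, 5)
  expect_true(perfect$lr_pos_infinite)
  expect_equal(perfect$lr_neg, 0)

  dm2 <- diagnostic_metrics(3, 1, 1, 3)
  expect_equal(dm2$sens, 75)
  expect_equal(dm2$lr_pos, 3)
  expect_equal(dm2$lr_neg, 1 / 3)
  # beta-quantile oracle for the exact bounds
  expect_equal(dm2$sens_ci[["lower"]], 100 * qbeta(0.025, 3, 2),
               tolerance = 1e-6)
  expect_equal(dm2$sens_ci[["upper"]], 100 * qbeta(0.975, 4, 1),
               tolerance = 1e-6)
})

test_that("exact binomial bounds match their boundary closed forms", {
  for (n in c(1, 5, 10, 14, 37)) {
    expect_equal(clopper_pearson(n, n)[["lower"]], 0.025^(1 / n),
                 tolerance = 1e-10)
    expect_equal(clopper_pearson(n, n)[["upper"]], 1)
    expect_equal(clopper_pearson(0, n)[["upper"]], 1 - 0.025^(1 / n),
                 tolerance = 1e-10)
    expect_equal(clopper_pearson(0, n)[["lower"]], 0)
  }
})

test_that("AUC equals brute-force pair counting", {
  expect_error(auc_with_ci(c(3, 5), c(TRUE, TRUE)), "both classes")
  expect_equal(auc_with_ci(c(10, 11, 1, 2),
                           c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # cases (3, 5) vs controls (1, 4): pairs 3>1, 3<4, 5>1, 5>4 -> 3 of 4
  expect_equal(auc_with_ci(c(3, 5, 1, 4),
                           c(TRUE, TRUE, FALSE, FALSE))$auc, 3 / 4)
  expect_equal(oracle_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)), 3 / 4)

  set.seed(91)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    labs <- runif(n) < 0.5
    if (!any(labs) || all(labs)) next
    sc <- sample(1:6, n, replace = TRUE)  # heavy ties on purpose
    expect_equal(auc_with_ci(sc, labs)$auc, oracle_auc(sc, labs))
  }
})

test_that("AUC flips exactly under score negation", {
  set.seed(92)
  sc <- sample(1:8, 30, replace = TRUE)
  labs <- runif(30) < 0.4
  labs[1:2] <- c(TRUE, FALSE)
  expect_equal(auc_with_ci(sc, labs)$auc + auc_with_ci(-sc, labs)$auc, 1)
})

test_that("DeLong interval agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(93)
  for (i in 1:10) {
    labs <- rep(c(TRUE, FALSE), c(20, 30))
    sc <- rnorm(50, mean = labs)
    ours <- auc_with_ci(sc, labs)
    ref <- suppressMessages(pROC::roc(labs, sc, direction = "<",
                                      quiet = TRUE))
    ref_ci <- as.numeric(suppressWarnings(pROC::ci.auc(ref,
                                                       method = "delong")))
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
    expect_equal(unname(ours$ci), ref_ci[c(1, 3)], tolerance = 1e-8)
  }
})

test_that("the untruncated interval can leave the unit range, flagged", {
  sc <- c(5, 6, 7, 8, 1, 2, 3, 9)
  labs <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  na <- auc_with_ci(sc, labs, method = "normal-approx")
  dl <- auc_with_ci(sc, labs, method = "delong")
  expect_gt(na$ci[["upper"]], 1)
  expect_true(na$out_of_range)
  expect_lte(dl$ci[["upper"]], 1)
})

test_that("paired AUC comparison is symmetric and null on identical scores", {
  set.seed(94)
  labs <- rep(c(TRUE, FALSE), c(10, 12))
  a <- rnorm(22, mean = labs)
  b <- a + rnorm(22, sd = 0.5)
  same <- compare_auc(a, a, labs)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  ab <- compare_auc(a, b, labs)
  ba <- compare_auc(b, a, labs)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p, ba$p)
})

test_that("paired DeLong comparison agrees with pROC's roc.test", {
  skip_if_not_installed("pROC")
  set.seed(95)
  labs <- rep(c(TRUE, FALSE), c(15, 20))
  a <- rnorm(35, mean = labs)
  b <- rnorm(35, mean = 0.5 * labs)
  ours <- compare_auc(a, b, labs)
  ra <- pROC::roc(labs, a, direction = "<", quiet = TRUE)
  rb <- pROC::roc(labs, b, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-8)
})

test_that("DeLong variance shrinks consistently under sample duplication", {
  set.seed(96)
  labs <- rep(c(TRUE, FALSE), c(12, 15))
  sc <- rnorm(27, mean = labs)
  v1 <- auc_with_ci(sc, labs)$se^2
  v2 <- auc_with_ci(rep(sc, 2), rep(labs, 2))$se^2
  # duplicating every subject doubles m and n; component variances are
  # nearly unchanged (duplication changes the denominator m-1 -> 2m-1)
  expect_lt(abs(v2 - v1 / 2) / (v1 / 2), 0.06)
})

test_that("model evaluation reports rows per model and dataset", {
  coh <- generate_cohort(strong_effects_config(n = 400, seed = 29))
  derived <- build_index(coh, c("th17", "b_cells", "tlr2_mfi"))
  rep_ <- suppressWarnings(
    evaluate_models(coh, list(LIPI = lipi_default_index(),
                              derived = derived)))
  expect_setequal(unique(rep_$dataset), c("baseline", "nested"))
  expect_equal(nrow(rep_), 4L)
  expect_true(all(rep_$sens >= 0 & rep_$sens <= 100))
  expect_true(all(rep_$auc >= 0 & rep_$auc <= 1))

  one <- suppressWarnings(
    evaluate_models(coh, list(only = derived), datasets = "baseline"))
  expect_equal(nrow(one), 1L)

  # zero-infection cohort: every row fails, and that is an error
  p0 <- coh$patients
  p0$infected <- FALSE
  p0$infection_day <- NA_real_
  p0$severe <- NA
  coh0 <- lipi_cohort(coh$visits, p0, coh$features)
  expect_error(suppressWarnings(
    evaluate_models(coh0, list(LIPI = lipi_default_index()))), "no model")
})

test_that("performance reports serialize to TSV", {
  coh <- generate_cohort(strong_effects_config(n = 300, seed = 31))
  rep_ <- suppressWarnings(
    evaluate_models(coh, list(LIPI = lipi_default_index()),
                    datasets = "baseline"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_performance(rep_, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(rep_))
  expect_equal(back$auc, rep_$auc)
})
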