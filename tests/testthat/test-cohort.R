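test_that("cohort CSV round-trip is the identity on valid cohorts", {
  coh <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- load_cohort(path)
  expect_equal(back$features, coh$features)
  expect_equal(back$visits[coh$features], coh$visits[coh$features])
  expect_equal(back$visits$day, coh$visits$day)
  expect_equal(back$patients$infected, coh$patients$infected)
  expect_equal(back$patients$infection_day, coh$patients$infection_day)
})

test_that("schema and invariant violations are rejected with named errors", {
  coh <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)

  df <- read.csv(path, check.names = FALSE)
  df$day <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_error(load_cohort(path2), "day")

  bad <- tiny_cohort()
  p <- bad$patients
  p$infection_day[1] <- 400  # beyond followup_days = 365
  expect_error(lipi_cohort(bad$visits, p, bad$features), "followup")

  v <- coh$visits
  v2 <- rbind(v, v[1, ])  # duplicate (patient, day)
  expect_error(lipi_cohort(v2, coh$patients, coh$features), "duplicate")

  df <- read.csv(path, check.names = FALSE)
  df$th17[2] <- "oops"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path3, row.names = FALSE)
  expect_error(load_cohort(path3), "th17")
})

test_that("feature summaries use type-7 quartiles and respect groups", {
  visits <- data.frame(patient_id = paste0("P", 1:5), day = 0,
                       x = c(1, 2, 3, 4, 5), drugs = "",
                       stringsAsFactors = FALSE)
  patients <- data.frame(patient_id = paste0("P", 1:5),
                         infected = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                         infection_day = c(100, 200, NA, NA, NA),
                         followup_days = 365, stringsAsFactors = FALSE)
  coh <- lipi_cohort(visits, patients, "x")
  s <- summarize_feature(coh, "x")
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$n, 5)

  # identical values in both groups -> identical medians
  visits$x <- 7
  coh7 <- lipi_cohort(visits, patients, "x")
  s7 <- summarize_feature(coh7, "x", group = "infected")
  expect_equal(s7$median, c(7, 7))

  # permutation invariance of the quartiles
  visits$x <- c(9, 1, 6, 2, 8)
  perm <- visits[c(4, 1, 5, 3, 2), ]
  expect_equal(summarize_feature(lipi_cohort(perm, patients, "x"), "x"),
               summarize_feature(lipi_cohort(visits, patients, "x"), "x"))
})

test_that("summaries of generated features recover the target median", {
  coh <- generate_cohort(generator_config(n_patients = 1000, seed = 42))
  s <- summarize_feature(coh, "th17")
  expect_lt(abs(s$median - 4) / 4, 0.10)
})

test_that("unpaired comparison matches exhaustive permutation enumeration", {
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  res <- compare_groups(x, y)
  expect_equal(res$statistic, 0)  # U = 0: complete separation
  expect_equal(res$p, oracle_mw_p(x, y))

  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- round(rnorm(n1), 4); y <- round(rnorm(n2, 1), 4)  # no ties a.s.
    expect_equal(compare_groups(x, y)$p, oracle_mw_p(x, y))
  }
})

test_that("chi-square variant reproduces the closed-form Pearson sum", {
  x <- c(4, 2); y <- c(14, 35)
  res <- suppressWarnings(compare_groups(x, y, type = "chisq"))
  tab <- rbind(x, y)
  expe <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expe)^2 / expe))
})

test_that("degenerate paired comparison warns and returns p = 1", {
  x <- c(3, 5, 8)
  expect_warning(res <- compare_groups(x, x, paired = TRUE), "zero")
  expect_equal(res$p, 1)
  expect_error(compare_groups(1:4, 1:3, paired = TRUE), "equal lengths")
})

test_that("adjusted mean disease activity is the trapezoidal time average", {
  expect_equal(adjusted_mean_sledai(0, 12), 12)
  expect_equal(adjusted_mean_sledai(c(0, 180), c(12, 4)), 8)
  expect_equal(adjusted_mean_sledai(c(0, 30, 180), c(10, 10, 0)),
               (10 * 30 + 5 * 150) / 180)
  # constant series equals the constant for any spacing
  set.seed(3)
  for (i in 1:5) {
    d <- sort(sample(0:365, sample(2:6, 1)))
    expect_equal(adjusted_mean_sledai(d, rep(7, length(d))), 7)
  }
  # step rule carries scores forward
  expect_equal(adjusted_mean_sledai(c(0, 30, 180), c(10, 10, 0),
                                    method = "step"), 10)
})

test_that("exposure summaries use the printed prednisone boundaries", {
  expect_equal(as.character(prednisone_category(c(7.5, 7.6, 30, 30.1))),
               c("low", "medium", "medium", "high"))
  coh <- tiny_cohort()
  expect_true(summarize_exposure(coh, "A", "cyclophosphamide")$any_use)
  expect_false(summarize_exposure(coh, "B", "cyclophosphamide")$any_use)
  eC <- summarize_exposure(coh, "C", "azathioprine")
  expect_true(eC$any_use)
  expect_equal(length(eC$prednisone_category), 2L)
  expect_equal(as.character(eC$prednisone_category), c("high", "high"))
})

test_that("NET density is the mean per-field structures per 100 cells", {
  expect_equal(net_density(rep(3, 6), rep(30, 6)), 10)
  expect_equal(net_density(rep(0, 6), rep(25, 6)), 0)
  expect_equal(net_density(c(1, 2, 3, 0, 2, 4), rep(20, 6)), 10)
  expect_error(net_density(c(1, 2), c(20, 0)), "cell")
})
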