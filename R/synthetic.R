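#' Feature distribution specification
#'
#' A positive-valued feature summarised as median (IQR), as published
#' cohort tables print it, to be emulated by a log-normal marginal.
#'
#' @param feature feature name.
#' @param median,q1,q3 published median and quartiles; `0 < q1 <= median <= q3`.
#' @return a `lipi_dist_spec` list.
#' @export
feature_dist_spec <- function(feature, median, q1, q3) {
  if (!(q1 > 0 && q1 <= median && median <= q3))
    stop("need 0 < q1 <= median <= q3 for feature ", feature, call. = FALSE)
  structure(list(feature = feature, median = median, q1 = q1, q3 = q3,
                 family = "lognormal"),
            class = "lipi_dist_spec")
}

#' Fit a log-normal from published quartiles
#'
#' Moment-free fit to a printed "median (IQR)" summary: `mu = log(median)`;
#' each quartile gives a one-sided scale estimate
#' `sigma_hi = log(q3/median)/z` and `sigma_lo = log(median/q1)/z` with
#' `z = qnorm(0.75)`, and `sigma` is their mean (printed quartiles of
#' skewed counts are asymmetric; averaging is the minimal symmetric
#' compromise, and both one-sided fits are retained).
#'
#' @param spec a [feature_dist_spec()].
#' @return list with `mu`, `sigma`, `sigma_lo`, `sigma_hi`, `degenerate`.
#' @export
fit_lognormal_from_quartiles <- function(spec) {
  stopifnot(inherits(spec, "lipi_dist_spec"))
  z <- stats::qnorm(0.75)
  mu <- log(spec$median)
  sigma_hi <- log(spec$q3 / spec$median) / z
  sigma_lo <- log(spec$median / spec$q1) / z
  sigma <- mean(c(sigma_lo, sigma_hi))
  list(mu = mu, sigma = sigma, sigma_lo = sigma_lo, sigma_hi = sigma_hi,
       degenerate = sigma == 0)
}

#' Published feature summaries as distribution presets
#'
#' Median/IQR presets for the immunological features the index is built
#' from, taken from the published cohort summaries: `"cohort"` (the whole
#' lupus cohort at baseline), `"infection"` / `"no_infection"` (baseline
#' values split by the prospective outcome) and `"nested_infection"` /
#' `"nested_no_infection"` (the distributional columns of the score-rule
#' table, which differ from the baseline split and are exposed as an
#' alternative preset rather than merged).
#'
#' @param preset which published summary column to emulate.
#' @return list of [feature_dist_spec()].
#' @export
lipi_feature_specs <- function(preset = c("cohort", "infection",
                                          "no_infection",
                                          "nested_infection",
                                          "nested_no_infection")) {
  preset <- match.arg(preset)
  tab <- switch(preset,
    cohort = list(
      c(4, 2, 10.5),          # th17
      c(163.5, 55.75, 352.25),# b_cells
      c(9567, 5552, 13848),   # tlr2_mfi
      c(43, 19, 110),         # ldg
      c(1084, 686, 1659)),    # lymphocytes
    infection = list(
      c(11, 4, 43),
      c(88, 16, 254),
      c(11553, 1436, 18625),
      c(105, 34, 331),
      c(989, 557, 1697)),
    no_infection = list(
      c(3, 2, 4),
      c(253, 97, 381),
      c(9538, 5976, 12074),
      c(32, 14, 77),
      c(1117, 720, 1655)),
    nested_infection = list(
      c(11, 6, 43),
      c(47, 14.75, 105),
      c(1640, 1362, 8292),
      c(105, 34, 331),
      c(989, 557, 1697)),
    nested_no_infection = list(
      c(3, 2, 4),
      c(157, 68, 256),
      c(8396, 1348, 13012),
      c(32, 14, 77),
      c(1117, 720, 1655)))
  nm <- c("th17", "b_cells", "tlr2_mfi", "ldg", "lymphocytes")
  out <- mapply(function(n, v) feature_dist_spec(n, v[1], v[2], v[3]),
                nm, tab, SIMPLIFY = FALSE)
  names(out) <- nm
  out
}

#' Synthetic cohort generator configuration
#'
#' Defaults reproduce the study conditions: 55 patients followed one year
#' on the 0/30/90/180-day visit schedule, a 32.7% one-year infection
#' incidence, 6/55 cyclophosphamide exposure, and feature marginals from
#' the published cohort medians/IQRs.  The outcome acts through the four
#' index variables on the log-feature scale, in the published directions.
#'
#' @param n_patients number of patients (>= 2).
#' @param dist_specs list of [feature_dist_spec()]; default
#'   `lipi_feature_specs("cohort")`.
#' @param effects named numeric: logistic coefficients on log-transformed
#'   features.
#' @param binary_effects named numeric: logistic coefficients for drug
#'   exposures.
#' @param target_prevalence expected infection fraction, in (0, 1).
#' @param visit_days ascending integer schedule starting at 0.
#' @param cyc_fraction fraction of patients exposed to cyclophosphamide.
#' @param icc within-patient intraclass correlation of log feature values
#'   across visits (one shared patient-level log-scale deviation).
#' @param followup_days follow-up window length in days.
#' @param seed integer RNG seed used by [generate_cohort()].
#' @return a `lipi_generator_config` list.
#' @export
generator_config <- function(n_patients = 55,
                             dist_specs = lipi_feature_specs("cohort"),
                             effects = c(th17 = 0.8, b_cells = -0.8,
                                         tlr2_mfi = -0.5),
                             binary_effects = c(cyclophosphamide = 1.3),
                             target_prevalence = 0.327,
                             visit_days = c(0, 30, 90, 180),
                             cyc_fraction = 6 / 55,
                             icc = 0.5,
                             followup_days = 365,
                             seed = 1L) {
  stopifnot(n_patients >= 2,
            target_prevalence > 0, target_prevalence < 1,
            icc >= 0, icc <= 1,
            cyc_fraction >= 0, cyc_fraction <= 1)
  if (visit_days[1] != 0 || is.unsorted(visit_days, strictly = TRUE))
    stop("visit_days must be strictly ascending and start at 0",
         call. = FALSE)
  feat <- vapply(dist_specs, `[[`, character(1), "feature")
  if (length(bad <- setdiff(names(effects), feat)) > 0L)
    stop("effects reference unknown feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 dist_specs = dist_specs, effects = effects,
                 binary_effects = binary_effects,
                 target_prevalence = target_prevalence,
                 visit_days = as.integer(visit_days),
                 cyc_fraction = cyc_fraction, icc = icc,
                 followup_days = as.integer(followup_days),
                 seed = as.integer(seed)),
            class = "lipi_generator_config")
}

#' Read / write a generator configuration as JSON
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @return `read_generator_config` returns the config; `write_generator_config`
#'   returns `path` invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "lipi_generator_config"))
  x <- unclass(config)
  x$dist_specs <- unname(lapply(x$dist_specs, unclass))
  x$effects <- as.list(x$effects)          # keep names in JSON objects
  x$binary_effects <- as.list(x$binary_effects)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(x$dist_specs)), function(i)
    feature_dist_spec(x$dist_specs$feature[i], x$dist_specs$median[i],
                      x$dist_specs$q1[i], x$dist_specs$q3[i]))
  names(specs) <- x$dist_specs$feature
  generator_config(n_patients = x$n_patients, dist_specs = specs,
                   effects = unlist(x$effects),
                   binary_effects = unlist(x$binary_effects),
                   target_prevalence = x$target_prevalence,
                   visit_days = x$visit_days,
                   cyc_fraction = x$cyc_fraction, icc = x$icc,
                   followup_days = x$followup_days, seed = x$seed)
}

# calibrate the logistic intercept by bisection on the sampled linear
# predictors so that mean(plogis(a + lp)) == target
calibrate_intercept <- function(lp, target) {
  if (target <= 0 || target >= 1)
    stop("unsatisfiable prevalence target: ", target, call. = FALSE)
  f <- function(a) mean(stats::plogis(a + lp)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("intercept calibration failed: target prevalence unreachable",
         call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort
#'
#' Deterministic given the config seed.  Per patient, each feature follows
#' a log-normal fitted from its published quartiles; visits within a
#' patient share one log-scale Gaussian deviation (intraclass correlation
#' `icc`).  Infection is drawn from a logistic model on the baseline
#' log-features and drug exposures, with the intercept calibrated by
#' bisection so the expected prevalence equals `target_prevalence`;
#' infected patients receive an infection day uniform over follow-up.
#'
#' @param config a [generator_config()].
#' @param seed optional override of `config$seed`.
#' @return a [lipi_cohort()].
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "lipi_generator_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  n <- config$n_patients
  nv <- length(config$visit_days)
  feat <- vapply(config$dist_specs, `[[`, character(1), "feature")
  fits <- lapply(config$dist_specs, fit_lognormal_from_quartiles)
  names(fits) <- feat

  ids <- sprintf("P%04d", seq_len(n))
  visits <- data.frame(
    patient_id = rep(ids, each = nv),
    day = rep(config$visit_days, times = n),
    stringsAsFactors = FALSE)

  for (f in feat) {
    mu <- fits[[f]]$mu; sigma <- fits[[f]]$sigma
    u <- stats::rnorm(n, 0, sigma * sqrt(config$icc))
    e <- stats::rnorm(n * nv, 0, sigma * sqrt(1 - config$icc))
    visits[[f]] <- exp(mu + rep(u, each = nv) + e)
  }

  # treatment: cyclophosphamide for a fixed fraction, at every visit;
  # azathioprine sprinkled in for realism of the drugs column
  cyc <- stats::runif(n) < config$cyc_fraction
  aza <- stats::runif(n) < 0.3
  drugs_p <- ifelse(cyc & aza, "cyclophosphamide;azathioprine",
             ifelse(cyc, "cyclophosphamide",
             ifelse(aza, "azathioprine", "")))
  visits$drugs <- rep(drugs_p, each = nv)

  # disease activity and steroid dose: rounded log-normals at cohort-typical
  # medians (activity scores are inputs downstream, not modelled outcomes)
  visits$sledai <- round(stats::rlnorm(n * nv, log(8), 0.6))
  visits$bilag <- round(stats::rlnorm(n * nv, log(4.5), 0.8))
  visits$prednisone_mg_day <- round(stats::rlnorm(n * nv, log(15), 0.7), 1)

  # outcome from baseline (day 0) values
  base_idx <- seq(1, n * nv, by = nv)
  lp <- numeric(n)
  for (f in names(config$effects))
    lp <- lp + config$effects[[f]] * log(visits[[f]][base_idx])
  if ("cyclophosphamide" %in% names(config$binary_effects))
    lp <- lp + config$binary_effects[["cyclophosphamide"]] * cyc
  alpha <- calibrate_intercept(lp, config$target_prevalence)
  pr <- stats::plogis(alpha + lp)
  infected <- stats::runif(n) < pr
  infection_day <- ifelse(infected,
                          sample.int(config$followup_days, n, replace = TRUE),
                          NA_real_)
  severe <- ifelse(infected, stats::runif(n) < 0.263, NA)

  patients <- data.frame(patient_id = ids, infected = infected,
                         infection_day = infection_day, severe = severe,
                         followup_days = config$followup_days,
                         stringsAsFactors = FALSE)
  out <- lipi_cohort(visits, patients, feat)
  attr(out, "latent") <- list(linear_predictor = lp, prob = pr,
                              intercept = alpha, seed = seed)
  out
}

#' Nested case-control dataset
#'
#' For each infected patient, selects the latest visit whose day lies in
#' `[infection_day - window[2], infection_day - window[1]]` (the
#' measurement taken one to three months before the event).  Every
#' uninfected patient contributes one row: its visit at the same scheduled
#' visit index as the cases (the modal selected index when cases differ),
#' i.e. a control measurement at the same follow-up time.  Cases with no
#' visit in the window are dropped with a warning.
#'
#' @param cohort a [lipi_cohort()].
#' @param window days-before-infection window, closed, default `c(30, 90)`.
#' @return data.frame with columns `patient_id`, `case` (logical),
#'   `visit_index`, `day`, the feature columns and drug exposure columns;
#'   class `lipi_nested`.
#' @export
generate_nested_case_control <- function(cohort, window = c(30, 90)) {
  stopifnot(inherits(cohort, "lipi_cohort"), length(window) == 2L,
            window[1] <= window[2])
  p <- cohort$patients
  if (!any(p$infected) || !any(!p$infected))
    stop("nested case-control needs at least one infected and one ",
         "uninfected patient", call. = FALSE)
  v <- cohort$visits
  expo <- baseline_table(cohort)
  drug_cols <- setdiff(names(expo),
                       c("patient_id", "infected", cohort$features))
  take <- function(pid, idx, is_case) {
    vv <- v[v$patient_id == pid, , drop = FALSE]
    idx <- min(idx, nrow(vv))
    r <- data.frame(patient_id = pid, case = is_case, visit_index = idx,
                    day = vv$day[idx], stringsAsFactors = FALSE)
    for (f in cohort$features) r[[f]] <- vv[[f]][idx]
    for (d in drug_cols) r[[d]] <- expo[[d]][expo$patient_id == pid]
    r
  }

  rows <- list()
  sel_idx <- integer(0)
  dropped <- character(0)
  for (id in p$patient_id[p$infected]) {
    inf_day <- p$infection_day[p$patient_id == id]
    pv <- v[v$patient_id == id, , drop = FALSE]
    ok <- which(pv$day >= inf_day - window[2] & pv$day <= inf_day - window[1])
    if (length(ok) == 0L) { dropped <- c(dropped, id); next }
    sel <- ok[which.max(pv$day[ok])]  # latest eligible visit
    sel_idx <- c(sel_idx, sel)
    rows[[length(rows) + 1L]] <- take(id, sel, TRUE)
  }
  if (length(dropped) > 0L)
    warning("case(s) without a visit in the pre-infection window dropped: ",
            paste(dropped, collapse = ", "))
  if (length(rows) == 0L)
    stop("no eligible case has a visit in the pre-infection window",
         call. = FALSE)
  modal <- as.integer(names(which.max(table(sel_idx))))
  for (cid in p$patient_id[!p$infected])
    rows[[length(rows) + 1L]] <- take(cid, modal, FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lipi_nested", "data.frame")
  out
}
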