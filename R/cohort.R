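#' Longitudinal lupus cohort container
#'
#' A `lipi_cohort` holds one row per (patient, visit) together with a
#' patient-level outcome table.  Feature values are stored exactly as
#' measured (cell counts in 1e6/L, fluorescence intensities in arbitrary
#' units, percentages in %); no unit conversion happens inside the pipeline.
#'
#' @param visits data.frame with columns `patient_id`, `day`, `sledai`,
#'   `bilag`, `prednisone_mg_day`, `drugs` (semicolon-separated drug names,
#'   possibly empty) and one numeric column per feature.
#' @param patients data.frame with columns `patient_id`, `infected`
#'   (logical), `infection_day` (integer or NA), `severe` (logical or NA),
#'   `followup_days` (integer).
#' @param features character vector naming the feature columns of `visits`.
#'
#' @return An object of class `lipi_cohort`: a list with elements `visits`,
#'   `patients` and `features`.
#' @export
lipi_cohort <- function(visits, patients, features) {
  stopifnot(is.data.frame(visits), is.data.frame(patients),
            is.character(features))
  visits <- as.data.frame(visits)
  patients <- as.data.frame(patients)

  required_v <- c("patient_id", "day")
  required_p <- c("patient_id", "infected", "followup_days")
  miss_v <- setdiff(required_v, names(visits))
  miss_p <- setdiff(required_p, names(patients))
  if (length(miss_v) > 0L)
    stop("visit table lacks required column(s): ",
         paste(miss_v, collapse = ", "), call. = FALSE)
  if (length(miss_p) > 0L)
    stop("patient table lacks required column(s): ",
         paste(miss_p, collapse = ", "), call. = FALSE)
  miss_f <- setdiff(features, names(visits))
  if (length(miss_f) > 0L)
    stop("feature(s) not present in visit table: ",
         paste(miss_f, collapse = ", "), call. = FALSE)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patient table", call. = FALSE)
  if (anyDuplicated(visits[c("patient_id", "day")]))
    stop("duplicate (patient_id, day) visit rows", call. = FALSE)
  if (any(visits$day < 0))
    stop("visit day must be >= 0", call. = FALSE)
  for (f in features) {
    v <- visits[[f]]
    if (!is.numeric(v))
      stop("feature column is not numeric: ", f, call. = FALSE)
    if (any(v < 0, na.rm = TRUE))
      stop("negative values in feature: ", f, call. = FALSE)
  }
  if (!is.null(visits$sledai) && any(visits$sledai < 0, na.rm = TRUE))
    stop("sledai must be >= 0", call. = FALSE)
  if (!is.null(visits$bilag) && any(visits$bilag < 0, na.rm = TRUE))
    stop("bilag must be >= 0", call. = FALSE)
  if (is.null(visits$drugs)) visits$drugs <- ""
  visits$drugs[is.na(visits$drugs)] <- ""

  extra <- setdiff(unique(visits$patient_id), patients$patient_id)
  if (length(extra) > 0L)
    stop("visit rows for unknown patient(s): ",
         paste(extra, collapse = ", "), call. = FALSE)

  patients$infected <- as.logical(patients$infected)
  if (is.null(patients$infection_day)) patients$infection_day <- NA_real_
  if (is.null(patients$severe)) patients$severe <- NA
  bad <- !patients$infected & !is.na(patients$infection_day)
  if (any(bad))
    stop("infection_day present for uninfected patient(s): ",
         paste(patients$patient_id[bad], collapse = ", "), call. = FALSE)
  bad <- patients$infected &
    (is.na(patients$infection_day) |
       patients$infection_day < 0 |
       patients$infection_day > patients$followup_days)
  if (any(bad))
    stop("infection_day missing or outside [0, followup_days] for: ",
         paste(patients$patient_id[bad], collapse = ", "), call. = FALSE)

  # order visits by patient then day
  visits <- visits[order(match(visits$patient_id, patients$patient_id),
                         visits$day), , drop = FALSE]
  rownames(visits) <- NULL
  rownames(patients) <- NULL

  structure(list(visits = visits, patients = patients,
                 features = features),
            class = "lipi_cohort")
}

#' @export
print.lipi_cohort <- function(x, ...) {
  cat("Longitudinal cohort:", nrow(x$patients), "patients,",
      nrow(x$visits), "visits,", length(x$features), "features\n")
  cat("Infected:", sum(x$patients$infected), "of", nrow(x$patients),
      sprintf("(%.1f%%)\n", 100 * mean(x$patients$infected)))
  cat("Features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

# column layout of the cohort CSV dialect
.cohort_fixed_cols <- c("patient_id", "day", "infected", "infection_day",
                        "severe", "followup_days", "sledai", "bilag",
                        "prednisone_mg_day", "drugs")

#' Read a cohort CSV
#'
#' One row per (patient, visit); patient-level columns (`infected`,
#' `infection_day`, `severe`, `followup_days`) are repeated on every row and
#' must be constant within a patient.  All columns after the fixed block are
#' treated as features unless `features` is given.
#'
#' @param path path to a CSV file (UTF-8, "." decimal separator, header).
#' @param features optional character vector restricting which trailing
#'   columns are features.
#' @return a [lipi_cohort()].
#' @export
load_cohort <- function(path, features = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  miss <- setdiff(c("patient_id", "day", "infected", "followup_days"),
                  names(raw))
  if (length(miss) > 0L)
    stop("cohort CSV lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(features))
    features <- setdiff(names(raw), .cohort_fixed_cols)

  # row-level numeric diagnostics
  for (f in c("day", "followup_days", features)) {
    if (!f %in% names(raw)) next
    v <- raw[[f]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad) > 0L)
        stop("unparseable numeric value(s) in column '", f, "' at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      raw[[f]] <- num
    }
  }
  pid <- as.character(raw$patient_id)
  first <- !duplicated(pid)
  patients <- data.frame(
    patient_id = pid[first],
    infected = as.logical(raw$infected)[first],
    infection_day = if ("infection_day" %in% names(raw))
      as.numeric(raw$infection_day)[first] else NA_real_,
    severe = if ("severe" %in% names(raw))
      as.logical(raw$severe)[first] else NA,
    followup_days = as.numeric(raw$followup_days)[first],
    stringsAsFactors = FALSE)
  vis_cols <- intersect(c("patient_id", "day", "sledai", "bilag",
                          "prednisone_mg_day", "drugs", features),
                        names(raw))
  visits <- raw[vis_cols]
  visits$patient_id <- pid
  lipi_cohort(visits, patients, features)
}

#' Write a cohort CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, p))` reproduces
#' `x` up to column order.
#'
#' @param cohort a [lipi_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "lipi_cohort"))
  v <- cohort$visits
  p <- cohort$patients
  idx <- match(v$patient_id, p$patient_id)
  out <- data.frame(
    patient_id = v$patient_id,
    day = v$day,
    infected = p$infected[idx],
    infection_day = p$infection_day[idx],
    severe = p$severe[idx],
    followup_days = p$followup_days[idx],
    sledai = if (is.null(v$sledai)) NA else v$sledai,
    bilag = if (is.null(v$bilag)) NA else v$bilag,
    prednisone_mg_day = if (is.null(v$prednisone_mg_day)) NA
      else v$prednisone_mg_day,
    drugs = if (is.null(v$drugs)) "" else v$drugs,
    stringsAsFactors = FALSE, check.names = FALSE)
  for (f in cohort$features) out[[f]] <- v[[f]]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Baseline (first-visit) analysis table
#'
#' One row per patient carrying the features measured at the visit closest
#' to enrollment (smallest day), the infection outcome, and one logical
#' exposure column per drug ever recorded (any use over follow-up).
#'
#' @param cohort a [lipi_cohort()].
#' @return data.frame with `patient_id`, `infected`, feature columns and
#'   drug exposure columns.
#' @export
baseline_table <- function(cohort) {
  stopifnot(inherits(cohort, "lipi_cohort"))
  v <- cohort$visits
  p <- cohort$patients
  first <- !duplicated(v$patient_id)  # visits are day-sorted per patient
  base <- v[first, , drop = FALSE]
  base <- base[match(p$patient_id, base$patient_id), , drop = FALSE]
  out <- data.frame(patient_id = p$patient_id, infected = p$infected,
                    stringsAsFactors = FALSE)
  for (f in cohort$features) out[[f]] <- base[[f]]
  for (d in drug_catalog(cohort)) {
    any_use <- vapply(p$patient_id, function(id) {
      dv <- v$drugs[v$patient_id == id]
      any(d %in% unlist(strsplit(dv, ";", fixed = TRUE)))
    }, logical(1))
    out[[d]] <- unname(any_use)
  }
  rownames(out) <- NULL
  out
}

drug_catalog <- function(cohort) {
  d <- unlist(strsplit(cohort$visits$drugs, ";", fixed = TRUE))
  sort(unique(d[nzchar(d)]))
}

#' Median / IQR feature summary
#'
#' Medians and quartiles (type-7 linear interpolation) of a feature,
#' computed on baseline values by default, optionally per group.
#'
#' @param cohort a [lipi_cohort()].
#' @param feature feature name.
#' @param group `NULL` for a single group, the name of a logical/factor
#'   patient-level column (e.g. `"infected"`), or a vector of group labels
#'   aligned with the patient table.
#' @param at `"baseline"` (first visit) or `"all"` (every visit).
#' @return data.frame with columns `group`, `n`, `median`, `q1`, `q3`.
#' @export
summarize_feature <- function(cohort, feature, group = NULL,
                              at = c("baseline", "all")) {
  stopifnot(inherits(cohort, "lipi_cohort"))
  at <- match.arg(at)
  if (!feature %in% cohort$features)
    stop("feature not in catalog: ", feature, call. = FALSE)
  if (at == "baseline") {
    tab <- baseline_table(cohort)
    vals <- tab[[feature]]
    ids <- tab$patient_id
  } else {
    vals <- cohort$visits[[feature]]
    ids <- cohort$visits$patient_id
  }
  g <- if (is.null(group)) rep("all", length(vals))
  else if (length(group) == 1L && is.character(group)) {
    gg <- cohort$patients[[group]]
    if (is.null(gg)) stop("unknown grouping column: ", group, call. = FALSE)
    as.character(gg)[match(ids, cohort$patients$patient_id)]
  } else as.character(group)[match(ids, cohort$patients$patient_id)]

  res <- lapply(split(vals, g), function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NULL)
    q <- stats::quantile(x, c(.25, .5, .75), type = 7, names = FALSE)
    data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
  })
  empty <- names(res)[vapply(res, is.null, logical(1))]
  if (length(empty) > 0L)
    stop("no non-missing values of '", feature, "' in group(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, res)
  out <- cbind(data.frame(group = names(res), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Two-group comparison
#'
#' Mann-Whitney U test (unpaired), Wilcoxon signed-rank test (paired), or
#' Pearson chi-square on two count vectors.  Paired samples whose
#' differences are all zero return p = 1 with a warning (so batch table
#' generation never aborts on a degenerate column).
#'
#' @param x,y numeric samples (rank tests) or count vectors forming the two
#'   rows of a contingency table (`type = "chisq"`).
#' @param paired logical; signed-rank test when `TRUE`.
#' @param type `"auto"` (rank test chosen by `paired`), `"wilcoxon"` or
#'   `"chisq"`.
#' @param correct continuity correction for the chi-square variant
#'   (default `FALSE`, so the statistic equals the closed-form Pearson sum).
#' @return list with `statistic`, `p` and `method`.
#' @export
compare_groups <- function(x, y, paired = FALSE,
                           type = c("auto", "wilcoxon", "chisq"),
                           correct = FALSE) {
  type <- match.arg(type)
  if (type == "chisq") {
    tab <- rbind(x, y)
    ht <- stats::chisq.test(tab, correct = correct)
    return(list(statistic = unname(ht$statistic), p = ht$p.value,
                method = "chi-square"))
  }
  if (paired) {
    if (length(x) != length(y))
      stop("paired comparison requires equal lengths", call. = FALSE)
    if (length(x) < 3L) stop("need n >= 3 per group", call. = FALSE)
    d <- x - y
    if (all(d == 0)) {
      warning("all paired differences are zero; returning p = 1")
      return(list(statistic = 0, p = 1, method = "wilcoxon signed-rank"))
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    return(list(statistic = unname(ht$statistic), p = ht$p.value,
                method = "wilcoxon signed-rank"))
  }
  if (length(x) < 3L || length(y) < 3L)
    stop("need n >= 3 per group", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       method = "mann-whitney")
}

#' Time-weighted (adjusted) mean disease activity
#'
#' Adjusted mean SLEDAI over a patient's follow-up: the trapezoidal area
#' under the score-versus-day curve divided by the spanned days.  A single
#' visit returns that visit's score.  The `"step"` rule carries each score
#' forward to the next visit instead of interpolating.
#'
#' @param day integer visit days, ascending.
#' @param sledai scores at those days.
#' @param method `"trapezoid"` (default) or `"step"`.
#' @return the adjusted mean score.
#' @export
adjusted_mean_sledai <- function(day, sledai,
                                 method = c("trapezoid", "step")) {
  method <- match.arg(method)
  keep <- !is.na(sledai) & !is.na(day)
  day <- day[keep]; sledai <- sledai[keep]
  if (length(day) == 0L) stop("no visits with a score", call. = FALSE)
  if (is.unsorted(day, strictly = TRUE) && length(day) > 1L) {
    o <- order(day)
    day <- day[o]; sledai <- sledai[o]
  }
  if (length(day) == 1L) return(sledai)
  dt <- diff(day)
  span <- day[length(day)] - day[1]
  if (method == "trapezoid") {
    area <- sum((utils::head(sledai, -1) + utils::tail(sledai, -1)) / 2 * dt)
  } else {
    area <- sum(utils::head(sledai, -1) * dt)
  }
  area / span
}

#' Drug exposure summary for one patient
#'
#' `any_use` is TRUE when the drug appears at one or more visits; each
#' visit's prednisone dose is categorized as low (<= 7.5 mg/d), medium
#' (> 7.5 to 30 mg/d) or high (> 30 mg/d).
#'
#' @param cohort a [lipi_cohort()].
#' @param patient_id the patient.
#' @param drug drug name, e.g. `"cyclophosphamide"`.
#' @return list with `patient_id`, `drug`, `any_use` and
#'   `prednisone_category` (one category per visit).
#' @export
summarize_exposure <- function(cohort, patient_id,
                               drug = "cyclophosphamide") {
  stopifnot(inherits(cohort, "lipi_cohort"))
  v <- cohort$visits[cohort$visits$patient_id == patient_id, , drop = FALSE]
  if (nrow(v) == 0L) stop("unknown patient: ", patient_id, call. = FALSE)
  on <- vapply(strsplit(v$drugs, ";", fixed = TRUE),
               function(d) drug %in% d, logical(1))
  list(patient_id = patient_id, drug = drug, any_use = any(on),
       prednisone_category = prednisone_category(v$prednisone_mg_day))
}

#' Prednisone dose categories
#'
#' @param dose_mg_day daily dose in mg.
#' @return factor with levels low / medium / high (7.5 inclusive in low,
#'   30 inclusive in medium).
#' @export
prednisone_category <- function(dose_mg_day) {
  cut(dose_mg_day, breaks = c(-Inf, 7.5, 30, Inf),
      labels = c("low", "medium", "high"), right = TRUE)
}

#' NET density per 100 cells
#'
#' Mean over microscope fields of (fibrillar chromatin-elastase structures /
#' cells) * 100; typically six 40X fields per condition.
#'
#' @param structures structure counts per field.
#' @param cells cell counts per field; all must be > 0.
#' @return NETs per 100 cells.
#' @export
net_density <- function(structures, cells) {
  if (length(structures) != length(cells))
    stop("structures and cells must have equal length", call. = FALSE)
  if (any(cells <= 0))
    stop("every field must contain at least one cell", call. = FALSE)
  mean(structures / cells * 100)
}
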