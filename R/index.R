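#' Integer score rule
#'
#' One dichotomized component of a compound risk index: a binary exposure
#' (`kind = "binary-exposure"`, satisfied when the exposure is present) or
#' a dichotomized continuous feature (`kind = "dichotomized-continuous"`,
#' satisfied strictly above/below the cutoff per `direction`).
#'
#' @param feature feature or drug name.
#' @param kind `"binary-exposure"` or `"dichotomized-continuous"`.
#' @param direction `"greater"`, `"less"` or `"present"`.
#' @param cutoff finite numeric cutoff (dichotomized rules) or `NA`.
#' @param points positive integer points awarded when satisfied.
#' @return a `lipi_rule` list.
#' @export
score_rule <- function(feature, kind, direction, cutoff = NA_real_,
                       points = 1L) {
  kind <- match.arg(kind, c("binary-exposure", "dichotomized-continuous"))
  direction <- match.arg(direction, c("greater", "less", "present"))
  points <- as.integer(points)
  if (points < 1L) stop("points must be >= 1", call. = FALSE)
  if (kind == "dichotomized-continuous" && !is.finite(cutoff))
    stop("dichotomized rule needs a finite cutoff: ", feature,
         call. = FALSE)
  if (kind == "binary-exposure") direction <- "present"
  structure(list(feature = feature, kind = kind, direction = direction,
                 cutoff = cutoff, points = points),
            class = "lipi_rule")
}

#' Compound integer-point risk index
#'
#' @param rules list of [score_rule()].
#' @param threshold compound decision threshold: a score strictly above it
#'   predicts infection.  Default: points of the second-ranked rule minus
#'   0.5 (its own points minus 0.5 for a single-rule index), which
#'   reproduces the published 1.5 for the 3/2/1/1 point set.
#' @param name index name.
#' @return a `lipi_index` object.
#' @export
lipi_index <- function(rules, threshold = NULL, name = "index") {
  stopifnot(is.list(rules), length(rules) >= 1L,
            all(vapply(rules, inherits, logical(1), "lipi_rule")))
  pts <- sort(vapply(rules, `[[`, integer(1), "points"), decreasing = TRUE)
  if (is.null(threshold))
    threshold <- (if (length(pts) >= 2L) pts[2] else pts[1]) - 0.5
  if (threshold >= sum(pts))
    stop("threshold must be below the maximum score", call. = FALSE)
  structure(list(name = name, rules = rules, threshold = threshold),
            class = "lipi_index")
}

#' Assign integer points by risk-ratio rank
#'
#' Features are ranked by effect magnitude `max(RR, 1/RR)` in decreasing
#' order: the strongest association gets 3 points, the second 2, all
#' remaining features 1 — the published 3/2/1/1 pattern generalized
#' conservatively.  Protective features (RR < 1) keep their risk side on
#' the low end (direction `"less"`), so points always accrue on the risk
#' side.  A tie in magnitude across the 3/2 or 2/1 boundary is ambiguous
#' and raises an error demanding an explicit override.
#'
#' @param estimates `lipi_risk_estimate` data.frame (from
#'   [univariate_screen()] / [rr_from_2x2()]) or a named RR vector.
#' @return named integer vector of points, with attribute `direction`
#'   (`"greater"` for RR > 1, `"less"` for RR < 1).
#' @export
assign_points <- function(estimates) {
  if (is.numeric(estimates) && !is.null(names(estimates))) {
    rr <- estimates
  } else {
    stopifnot(is.data.frame(estimates))
    rr <- stats::setNames(estimates$rr, estimates$feature)
  }
  if (length(rr) < 1L) stop("need at least one estimate", call. = FALSE)
  if (any(rr <= 0)) stop("risk ratios must be positive", call. = FALSE)
  mag <- pmax(rr, 1 / rr)
  ord <- order(mag, decreasing = TRUE)
  m <- mag[ord]
  if (length(m) >= 2L && m[1] == m[2])
    stop("tied effect magnitudes at the 3-point boundary (",
         paste(names(m)[m == m[1]], collapse = ", "),
         "); supply points explicitly", call. = FALSE)
  if (length(m) >= 3L && m[2] == m[3])
    stop("tied effect magnitudes at the 2-point boundary (",
         paste(names(m)[m == m[2]], collapse = ", "),
         "); supply points explicitly", call. = FALSE)
  pts <- rep(1L, length(rr))
  pts[ord[1]] <- 3L
  if (length(rr) >= 2L) pts[ord[2]] <- 2L
  names(pts) <- names(rr)
  attr(pts, "direction") <- ifelse(rr >= 1, "greater", "less")
  pts
}

#' Derive a compound infection risk index from a cohort
#'
#' The fitting function of the package.  For each continuous feature it
#' estimates the infection risk ratio with a univariate screen, selects a
#' dichotomization cutoff on the empirical ROC curve by the
#' closest-to-corner criterion (on the risk side implied by the RR), and
#' assigns integer points by RR-magnitude rank ([assign_points()]); binary
#' drug exposures enter as present/absent rules with their 2x2 risk
#' ratio.  The compound decision threshold defaults to the second-ranked
#' rule's points minus 0.5.
#'
#' @param cohort a [lipi_cohort()].
#' @param features continuous feature names to screen.
#' @param binary_features drug exposure names (default
#'   `"cyclophosphamide"`; use `character(0)` for none).
#' @param dataset `"baseline"` (first-visit measurements) or `"nested"`
#'   (nested case-control measurements 1-3 months before infection).
#' @param p_max keep only features with screen p-value below this
#'   (default 1: the caller preselects features).
#' @param threshold optional explicit compound threshold.
#' @param name index name.
#' @param link link for the screen; defaults to `"logistic"` (see
#'   [univariate_screen()]).
#' @return a `lipi_index` with metadata: `estimates` (the screen),
#'   `dataset`, `call`.
#' @export
build_index <- function(cohort, features,
                        binary_features = "cyclophosphamide",
                        dataset = c("baseline", "nested"),
                        p_max = 1, threshold = NULL, name = "index",
                        link = "logistic") {
  stopifnot(inherits(cohort, "lipi_cohort"))
  dataset <- match.arg(dataset)
  data <- if (dataset == "baseline") baseline_table(cohort)
  else generate_nested_case_control(cohort)
  ycol <- if (dataset == "baseline") "infected" else "case"
  if (length(unique(data[[ycol]])) < 2L)
    stop("outcome has a single class; cannot derive an index",
         call. = FALSE)

  est <- NULL
  if (length(features) > 0L)
    est <- univariate_screen(features = features, data = data,
                             dataset = dataset, link = link)
  for (b in binary_features) {
    if (!b %in% names(data)) {
      warning("exposure '", b, "' not recorded in cohort; skipped")
      next
    }
    expo <- as.logical(data[[b]])
    y <- as.logical(data[[ycol]])
    e <- tryCatch(
      rr_from_2x2(sum(y & expo), sum(expo), sum(y & !expo), sum(!expo),
                  feature = b),
      error = function(err) {
        warning("exposure '", b, "' skipped: ", conditionMessage(err),
                call. = FALSE)
        NULL
      })
    if (!is.null(e)) { e$dataset <- dataset; est <- rbind(est, e) }
  }
  if (is.null(est) || nrow(est) == 0L)
    stop("no feature or exposure could be estimated", call. = FALSE)
  est <- est[est$p <= p_max, , drop = FALSE]
  if (nrow(est) == 0L)
    stop("no feature passed the p-value filter", call. = FALSE)

  pts <- assign_points(est)
  rules <- vector("list", nrow(est))
  for (i in seq_len(nrow(est))) {
    f <- est$feature[i]
    if (est$scale[i] == "binary") {
      rules[[i]] <- score_rule(f, "binary-exposure", "present",
                               points = pts[[f]])
    } else {
      dir <- attr(pts, "direction")[[f]]
      curve <- roc_points(data[[f]], data[[ycol]], direction = dir)
      cut <- closest_corner_cutoff(curve, feature = f)
      rules[[i]] <- score_rule(f, "dichotomized-continuous", dir,
                               cutoff = cut$threshold, points = pts[[f]])
    }
  }
  idx <- lipi_index(rules, threshold = threshold, name = name)
  idx$estimates <- est
  idx$dataset <- dataset
  idx$call <- match.call()
  idx
}

#' Score a single patient
#'
#' Applies the index rules to one patient's feature values with strict
#' inequalities at the cutoffs: a value exactly at a cutoff does not
#' satisfy the rule.
#'
#' @param x named list or vector of feature values; binary exposures as
#'   logicals (e.g. `cyclophosphamide = TRUE`).
#' @param index a `lipi_index`.
#' @return list with integer `score` and logical `predicted`
#'   (`score > threshold`).
#' @export
lipi_score <- function(x, index) {
  stopifnot(inherits(index, "lipi_index"))
  x <- as.list(x)
  need <- vapply(index$rules, `[[`, character(1), "feature")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L)
    stop("missing feature(s) for scoring: ", paste(miss, collapse = ", "),
         call. = FALSE)
  score <- 0L
  for (r in index$rules) {
    v <- x[[r$feature]]
    hit <- switch(r$direction,
                  present = isTRUE(as.logical(v)),
                  greater = is.finite(v) && v > r$cutoff,
                  less = is.finite(v) && v < r$cutoff)
    if (hit) score <- score + r$points
  }
  list(score = score, predicted = score > index$threshold)
}

#' @export
print.lipi_index <- function(x, ...) {
  cat("Compound risk index:", x$name, "\n")
  tab <- as.data.frame(summary(x))
  print(tab, row.names = FALSE)
  cat(sprintf("Decision threshold: score > %.1f predicts infection (max %d)\n",
              x$threshold, sum(vapply(x$rules, `[[`, integer(1), "points"))))
  invisible(x)
}

#' @export
summary.lipi_index <- function(object, ...) {
  rule_str <- vapply(object$rules, function(r) {
    switch(r$direction,
           present = "present",
           greater = paste(">", format(r$cutoff)),
           less = paste("<", format(r$cutoff)))
  }, character(1))
  out <- data.frame(
    feature = vapply(object$rules, `[[`, character(1), "feature"),
    rule = rule_str,
    points = vapply(object$rules, `[[`, integer(1), "points"),
    stringsAsFactors = FALSE)
  class(out) <- c("summary.lipi_index", "data.frame")
  out
}

#' @export
coef.lipi_index <- function(object, ...) {
  stats::setNames(vapply(object$rules, `[[`, integer(1), "points"),
                  vapply(object$rules, `[[`, character(1), "feature"))
}

#' Score patients with an index
#'
#' @param object a `lipi_index`.
#' @param newdata a [lipi_cohort()] (scored on baseline values and
#'   any-use drug exposure) or a data.frame with one column per rule
#'   feature (drug exposures as logicals).
#' @param ... unused.
#' @return data.frame with `patient_id` (when available), `score` and
#'   `predicted`.
#' @export
predict.lipi_index <- function(object, newdata, ...) {
  tab <- if (inherits(newdata, "lipi_cohort")) baseline_table(newdata)
  else as.data.frame(newdata)
  need <- vapply(object$rules, `[[`, character(1), "feature")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("missing feature(s) for scoring: ", paste(miss, collapse = ", "),
         call. = FALSE)
  res <- t(vapply(seq_len(nrow(tab)), function(i) {
    s <- lipi_score(tab[i, need, drop = FALSE], object)
    c(score = s$score, predicted = as.integer(s$predicted))
  }, numeric(2)))
  out <- data.frame(score = as.integer(res[, "score"]),
                    predicted = res[, "predicted"] == 1)
  if ("patient_id" %in% names(tab))
    out <- cbind(data.frame(patient_id = tab$patient_id,
                            stringsAsFactors = FALSE), out)
  out
}

#' The published four-variable infection predictive index
#'
#' The packaged index as published: cyclophosphamide use +3; Th17
#' count above 8 (1e6/L) +2; B cells below 60.5 (1e6/L) +1; TLR2 mean fluorescence
#' intensity in total monocytes below 1364 +1; a total score above 1.5 predicts
#' infection within the following year.
#'
#' @return a `lipi_index`.
#' @export
lipi_default_index <- function() {
  read_index(system.file("extdata", "lipi_v1.json", package = "lipir",
                         mustWork = TRUE))
}

#' Read / write an index definition as JSON
#'
#' @param index a `lipi_index`.
#' @param path file path.
#' @return `read_index` returns the index; `write_index` returns `path`
#'   invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "lipi_index"))
  x <- list(name = index$name, threshold = index$threshold,
            rules = lapply(index$rules, unclass))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rules <- lapply(x$rules, function(r)
    score_rule(r$feature, r$kind, r$direction,
               cutoff = if (is.null(r$cutoff)) NA_real_ else r$cutoff,
               points = r$points))
  lipi_index(rules, threshold = x$threshold, name = x$name)
}
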