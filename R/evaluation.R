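#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form: lower = `qbeta(alpha/2, x, n - x + 1)` (0 when
#' x = 0), upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n), so
#' the closed forms at the boundaries are `(alpha/2)^(1/n)` for x = n and
#' `1 - (alpha/2)^(1/n)` for x = 0.
#'
#' @param x successes.
#' @param n trials.
#' @param conf_level confidence level, default 0.95.
#' @return c(lower, upper) as proportions.
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(x >= 0, x <= n, n >= 1)
  a <- 1 - conf_level
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity and specificity (reported as percentages) with exact
#' Clopper-Pearson 95% CIs, and likelihood ratios
#' `LR+ = sens / (1 - spec)` (flagged infinite when spec = 1) and
#' `LR- = (1 - sens) / spec` (flagged undefined when spec = 0).  No
#' continuity correction by default; `correction = TRUE` adds 0.5 to every
#' cell before forming the likelihood ratios.
#'
#' @param tp,fn,fp,tn confusion counts; `tp + fn >= 1` and `fp + tn >= 1`.
#' @param alpha 1 - confidence level (default 0.05).
#' @param correction 0.5 continuity correction for the likelihood ratios.
#' @return list with `sens`, `sens_ci`, `spec`, `spec_ci` (percent),
#'   `lr_pos`, `lr_neg`, `lr_pos_infinite`, `lr_neg_undefined`, counts.
#' @export
diagnostic_metrics <- function(tp, fn, fp, tn, alpha = 0.05,
                               correction = FALSE) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0,
            tp + fn >= 1, fp + tn >= 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  sens_ci <- clopper_pearson(tp, tp + fn, 1 - alpha)
  spec_ci <- clopper_pearson(tn, tn + fp, 1 - alpha)
  if (correction) {
    s <- (tp + 0.5) / (tp + fn + 1)
    e <- (tn + 0.5) / (tn + fp + 1)
  } else {
    s <- sens; e <- spec
  }
  lr_pos_inf <- e == 1 && !correction
  lr_neg_undef <- e == 0 && !correction
  list(sens = 100 * sens, sens_ci = 100 * sens_ci,
       spec = 100 * spec, spec_ci = 100 * spec_ci,
       lr_pos = if (lr_pos_inf) Inf else s / (1 - e),
       lr_neg = if (lr_neg_undef) NaN else (1 - s) / e,
       lr_pos_infinite = lr_pos_inf, lr_neg_undefined = lr_neg_undef,
       counts = c(tp = tp, fn = fn, fp = fp, tn = tn))
}

# DeLong placement components: per-case and per-control structural values
# computed from midranks; auc = mean(V10) = mean(V01).
delong_components <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L)
    stop("both classes must be present", call. = FALSE)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = sum(r_all[seq_len(m)]) / (m * n) -
         (m + 1) / (2 * n))
}

#' AUC with confidence interval
#'
#' AUC by pairwise comparison (ties counted 1/2), equal to the probability
#' that a random case outscores a random control.  The CI uses the DeLong
#' variance; with `method = "delong"` the Wald interval is truncated to
#' the unit interval, with `method = "normal-approx"` it is left untruncated (the
#' convention behind published intervals whose upper bound exceeds 1) and
#' flagged when a bound leaves the unit interval.
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels logical (or 0/1) case indicator.
#' @param method `"delong"` (default) or `"normal-approx"`.
#' @param conf_level confidence level, default 0.95.
#' @return list with `auc`, `ci`, `se`, `p` (two-sided test of AUC = 0.5),
#'   `out_of_range` flag.
#' @export
auc_with_ci <- function(scores, labels, method = c("delong",
                                                   "normal-approx"),
                        conf_level = 0.95) {
  method <- match.arg(method)
  comp <- delong_components(scores, labels)
  auc <- comp$auc
  m <- length(comp$v10); n <- length(comp$v01)
  va <- if (m > 1L) stats::var(comp$v10) / m else 0
  vb <- if (n > 1L) stats::var(comp$v01) / n else 0
  se <- sqrt(va + vb)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- auc + c(-1, 1) * z * se
  oor <- ci[1] < 0 || ci[2] > 1
  if (method == "delong") ci <- pmin(pmax(ci, 0), 1)
  p <- if (se == 0) as.numeric(auc == 0.5)
  else 2 * stats::pnorm(-abs((auc - 0.5) / se))
  list(auc = auc, ci = stats::setNames(ci, c("lower", "upper")), se = se,
       p = min(p, 1), out_of_range = oor && method == "normal-approx")
}

#' Compare two AUCs (DeLong test)
#'
#' Paired (default): both score vectors are evaluated on the same
#' subjects/labels and the covariance of the placement components is used.
#' Unpaired: `labels_b` supplies the second sample's labels and the
#' variances add.  Identical paired score vectors give delta 0, p = 1.
#'
#' @param scores_a,scores_b score vectors.
#' @param labels case indicator for `scores_a` (and for `scores_b` when
#'   paired).
#' @param paired logical, default TRUE.
#' @param labels_b labels for `scores_b` when `paired = FALSE`.
#' @return list with `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
compare_auc <- function(scores_a, scores_b, labels, paired = TRUE,
                        labels_b = NULL) {
  ca <- delong_components(scores_a, labels)
  if (paired) {
    if (length(scores_b) != length(scores_a))
      stop("paired comparison requires equal-length score vectors",
           call. = FALSE)
    cb <- delong_components(scores_b, labels)
    m <- length(ca$v10); n <- length(ca$v01)
    v <- (if (m > 1L) stats::var(ca$v10 - cb$v10) / m else 0) +
      (if (n > 1L) stats::var(ca$v01 - cb$v01) / n else 0)
  } else {
    if (is.null(labels_b))
      stop("unpaired comparison needs labels_b", call. = FALSE)
    cb <- delong_components(scores_b, labels_b)
    va <- (if (length(ca$v10) > 1L) stats::var(ca$v10) / length(ca$v10) else 0) +
      (if (length(ca$v01) > 1L) stats::var(ca$v01) / length(ca$v01) else 0)
    vb <- (if (length(cb$v10) > 1L) stats::var(cb$v10) / length(cb$v10) else 0) +
      (if (length(cb$v01) > 1L) stats::var(cb$v01) / length(cb$v01) else 0)
    v <- va + vb
  }
  delta <- ca$auc - cb$auc
  se <- sqrt(v)
  z <- if (se == 0) 0 else delta / se
  p <- if (se == 0) (if (delta == 0) 1 else 0) else
    2 * stats::pnorm(-abs(z))
  list(auc_a = ca$auc, auc_b = cb$auc, delta = delta, se = se, z = z,
       p = min(p, 1))
}

#' Evaluate candidate indices on baseline and nested datasets
#'
#' One performance row per (model, dataset): confusion counts at the
#' index threshold, sensitivity/specificity with exact CIs, likelihood
#' ratios, AUC of the integer score with CI and a two-sided test against
#' AUC = 0.5.  Per-row failures are warnings, not errors; an empty report
#' is an error.
#'
#' @param cohort a [lipi_cohort()].
#' @param models named list of `lipi_index` objects (single-variable
#'   models are single-rule indices).
#' @param datasets subset of `c("baseline", "nested")`.
#' @param alpha 1 - confidence level.
#' @param auc_method passed to [auc_with_ci()].
#' @return a `lipi_performance` data.frame in the column order
#'   model, dataset, cutoff, lr_pos, lr_neg, auc (CI), sens (CI),
#'   spec (CI), p.
#' @export
evaluate_models <- function(cohort, models,
                            datasets = c("baseline", "nested"),
                            alpha = 0.05, auc_method = "delong") {
  stopifnot(inherits(cohort, "lipi_cohort"), is.list(models))
  datasets <- match.arg(datasets, several.ok = TRUE)
  if (is.null(names(models)))
    names(models) <- paste0("model", seq_along(models))
  rows <- list()
  for (ds in datasets) {
    tab <- tryCatch(
      if (ds == "baseline") baseline_table(cohort)
      else generate_nested_case_control(cohort),
      error = function(e) {
        warning("dataset '", ds, "' unavailable: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(tab)) next
    ycol <- if (ds == "baseline") "infected" else "case"
    y <- as.logical(tab[[ycol]])
    for (nm in names(models)) {
      row <- tryCatch({
        idx <- models[[nm]]
        sc <- predict(idx, tab)$score
        if (length(unique(y)) < 2L)
          stop("outcome has a single class", call. = FALSE)
        pred <- sc > idx$threshold
        dm <- diagnostic_metrics(sum(pred & y), sum(!pred & y),
                                 sum(pred & !y), sum(!pred & !y),
                                 alpha = alpha)
        au <- auc_with_ci(sc, y, method = auc_method,
                          conf_level = 1 - alpha)
        data.frame(model = nm, dataset = ds, cutoff = idx$threshold,
                   lr_pos = dm$lr_pos, lr_neg = dm$lr_neg,
                   auc = au$auc, auc_low = au$ci[1], auc_high = au$ci[2],
                   sens = dm$sens, sens_low = dm$sens_ci[1],
                   sens_high = dm$sens_ci[2],
                   spec = dm$spec, spec_low = dm$spec_ci[1],
                   spec_high = dm$spec_ci[2], p = au$p,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("model '", nm, "' on dataset '", ds, "' failed: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L)
    stop("no model could be evaluated on any dataset", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lipi_performance", "data.frame")
  out
}

#' @export
print.lipi_performance <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  fmt <- function(v, lo, hi)
    sprintf("%.*g (%.*g-%.*g)", digits, v, digits, lo, digits, hi)
  show <- data.frame(
    model = df$model, dataset = df$dataset, cutoff = df$cutoff,
    `LR+` = round(df$lr_pos, digits), `LR-` = round(df$lr_neg, digits),
    `AUC (CI)` = fmt(df$auc, df$auc_low, df$auc_high),
    `Sens (CI)` = fmt(df$sens, df$sens_low, df$sens_high),
    `Spec (CI)` = fmt(df$spec, df$spec_low, df$spec_high),
    p = signif(df$p, digits),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Write a performance report as TSV
#'
#' @param report a `lipi_performance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_performance <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
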