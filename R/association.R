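#' Risk ratio from a 2x2 table
#'
#' RR = (a/n1) / (c/n0) for `a` events among `n1` exposed and `c` events
#' among `n0` unexposed, with a log-scale Wald 95% CI,
#' `exp(log RR +/- z * sqrt(1/a - 1/n1 + 1/c - 1/n0))`, and the matching
#' two-sided Wald p-value.  With `correction = TRUE`, 0.5 is added to every
#' cell of the table before computing (for tables with zero cells).
#'
#' @param exposed_events,exposed_total events and total in the exposed arm.
#' @param unexposed_events,unexposed_total events and total in the
#'   unexposed arm.
#' @param conf_level confidence level, default 0.95.
#' @param correction add 0.5 to all four cells (off by default).
#' @return a `lipi_risk_estimate` data.frame row: `feature`, `rr`,
#'   `ci_low`, `ci_high`, `p`, `scale`.
#' @export
rr_from_2x2 <- function(exposed_events, exposed_total,
                        unexposed_events, unexposed_total,
                        conf_level = 0.95, correction = FALSE,
                        feature = "exposure") {
  stopifnot(exposed_total > 0, unexposed_total > 0,
            exposed_events <= exposed_total,
            unexposed_events <= unexposed_total)
  a <- exposed_events; b <- exposed_total - exposed_events
  c_ <- unexposed_events; d <- unexposed_total - unexposed_events
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  n1 <- a + b; n0 <- c_ + d
  if (a == 0 || c_ == 0)
    stop("zero events in one arm give an undefined RR; ",
         "enable the 0.5 continuity correction", call. = FALSE)
  rr <- (a / n1) / (c_ / n0)
  se <- sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(rr) + c(-1, 1) * z * se)
  p <- if (se == 0) 1 else 2 * stats::pnorm(-abs(log(rr) / se))
  risk_estimate(feature, rr, ci[1], ci[2], p, scale = "binary")
}

risk_estimate <- function(feature, rr, ci_low, ci_high, p,
                          dataset = NA_character_, scale = "per-unit") {
  out <- data.frame(feature = feature, rr = rr, ci_low = ci_low,
                    ci_high = ci_high, p = p, dataset = dataset,
                    scale = scale, stringsAsFactors = FALSE)
  class(out) <- c("lipi_risk_estimate", "data.frame")
  out
}

#' Fit a binary-outcome risk model
#'
#' Regression of an infection indicator on one or more features.  The
#' default `"auto"` link fits a log-binomial model (coefficients are log
#' risk ratios) and falls back to modified Poisson regression with a
#' robust (HC0 sandwich) variance when the log-binomial fit does not
#' converge; `"logistic"` reports odds ratios, labelled as such via the
#' `scale` column.  Wald 95% CIs and p-values throughout.
#'
#' @param formula model formula, e.g. `infected ~ th17`.
#' @param data data.frame with the outcome (logical or 0/1) and features.
#' @param link `"auto"`, `"log-binomial"`, `"modified-poisson"` or
#'   `"logistic"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return a `lipi_risk_model`: list with `features`, `link`, `loglik`,
#'   `k`, `aic`, `estimates` (per-feature `lipi_risk_estimate` rows,
#'   intercept excluded) and the underlying `fit`.
#' @export
fit_risk_model <- function(formula, data, link = c("auto", "log-binomial",
                                                   "modified-poisson",
                                                   "logistic"),
                           conf_level = 0.95) {
  link <- match.arg(link)
  mf <- stats::model.frame(formula, data = data)
  y <- as.numeric(stats::model.response(mf))
  if (length(unique(y)) < 2L)
    stop("outcome is constant; cannot fit a risk model", call. = FALSE)
  X <- stats::model.matrix(formula, data = mf)
  if (nrow(X) <= ncol(X))
    stop("need more observations than parameters", call. = FALSE)

  fit_one <- function(lnk) {
    if (lnk == "log-binomial") {
      start <- c(log(mean(y)), rep(0, ncol(X) - 1L))
      fit <- suppressWarnings(stats::glm.fit(
        X, y, family = stats::binomial(link = "log"), start = start))
      if (!fit$converged || any(!is.finite(fit$coefficients)))
        stop("log-binomial fit did not converge", call. = FALSE)
      vc <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
      list(fit = fit, vcov = vc, scale = "per-unit")
    } else if (lnk == "modified-poisson") {
      df <- as.data.frame(X[, -1, drop = FALSE])
      df$.y <- y
      fml <- stats::as.formula(paste(".y ~",
        if (ncol(df) > 1L) paste(sprintf("`%s`", setdiff(names(df), ".y")),
                                 collapse = " + ") else "1"))
      fit <- suppressWarnings(stats::glm(fml, data = df, family = stats::poisson()))
      list(fit = fit, vcov = sandwich::vcovHC(fit, type = "HC0"),
           scale = "per-unit")
    } else {  # logistic
      fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
      vc <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
      list(fit = fit, vcov = vc, scale = "odds")
    }
  }

  used <- link
  res <- if (link == "auto") {
    tryCatch({ used <- "log-binomial"; fit_one("log-binomial") },
             error = function(e) {
               used <<- "modified-poisson"
               fit_one("modified-poisson")
             })
  } else fit_one(link)

  cf <- stats::coef(res$fit)
  se <- sqrt(diag(res$vcov))
  names(se) <- names(cf)
  bad <- names(cf)[-1][abs(cf[-1]) > 20 | se[-1] > 100]
  if (length(bad) > 0L)
    stop("separation / non-convergence for feature(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  feats <- names(cf)[-1]
  est <- do.call(rbind, lapply(feats, function(f) {
    risk_estimate(gsub("`", "", f), exp(cf[[f]]),
                  exp(cf[[f]] - z * se[[f]]), exp(cf[[f]] + z * se[[f]]),
                  2 * stats::pnorm(-abs(cf[[f]] / se[[f]])),
                  scale = res$scale)
  }))

  ll <- if (inherits(res$fit, "glm")) as.numeric(stats::logLik(res$fit))
  else {
    mu <- pmin(pmax(res$fit$fitted.values, 1e-12), 1 - 1e-12)
    sum(stats::dbinom(y, 1, mu, log = TRUE))
  }
  k <- length(cf)
  structure(list(features = gsub("`", "", feats), link = used,
                 loglik = ll, k = k, aic = 2 * k - 2 * ll,
                 estimates = est, fit = res$fit, vcov = res$vcov),
            class = "lipi_risk_model")
}

#' @export
print.lipi_risk_model <- function(x, ...) {
  cat("Risk model (", x$link, "): ",
      paste(x$features, collapse = " + "), "\n", sep = "")
  cat(sprintf("logLik %.3f, k = %d, AIC %.3f\n", x$loglik, x$k, x$aic))
  if (!is.null(x$estimates)) print(as.data.frame(x$estimates), digits = 4)
  invisible(x)
}

#' Univariate infection-risk screen
#'
#' One single-feature risk model per feature, on the baseline table or a
#' nested case-control dataset; features whose fit fails (e.g. constant
#' value, separation) are skipped with a warning.  Results are sorted by
#' p-value.
#'
#' @param cohort a [lipi_cohort()], or `NULL` when `data` is supplied.
#' @param features feature names to screen.
#' @param dataset `"baseline"` or `"nested"`.
#' @param data optional pre-built analysis table (must contain an outcome
#'   column `infected` or `case` and the features); overrides `cohort`.
#' @param link passed to [fit_risk_model()]; the screen defaults to
#'   `"logistic"`, whose Wald test holds its nominal size under the
#'   heavy-tailed feature distributions this screen faces (log-binomial /
#'   modified-Poisson Wald tests are anticonservative there; they remain
#'   available for risk-ratio-scale estimation).
#' @return `lipi_risk_estimate` data.frame, one row per feature, sorted by
#'   `p`.
#' @export
univariate_screen <- function(cohort = NULL, features,
                              dataset = c("baseline", "nested"),
                              data = NULL, link = "logistic") {
  dataset <- match.arg(dataset)
  if (is.null(data)) {
    stopifnot(inherits(cohort, "lipi_cohort"))
    data <- if (dataset == "baseline") baseline_table(cohort)
    else generate_nested_case_control(cohort)
  }
  ycol <- if ("infected" %in% names(data)) "infected" else "case"
  if (length(unique(data[[ycol]][!is.na(data[[ycol]])])) < 2L)
    stop("outcome has a single class; cannot screen", call. = FALSE)
  rows <- list()
  for (f in features) {
    est <- tryCatch({
      d <- data[!is.na(data[[f]]) & !is.na(data[[ycol]]), , drop = FALSE]
      fml <- stats::as.formula(sprintf("%s ~ `%s`", ycol, f))
      m <- fit_risk_model(fml, d, link = link)
      m$estimates
    }, error = function(e) {
      warning("feature '", f, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(est)) {
      est$dataset <- dataset
      rows[[f]] <- est
    }
  }
  if (length(rows) == 0L)
    stop("no feature could be screened", call. = FALSE)
  out <- do.call(rbind, rows)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lipi_risk_estimate", "data.frame")
  out
}

#' Select an explanatory model by AIC
#'
#' Fits each candidate feature subset with [fit_risk_model()] and returns
#' the fit with the lowest AIC; ties are broken by fewer parameters, then
#' by lexicographic feature names.  Candidates that fail to fit are
#' collected; if all fail, an error lists the per-candidate causes.
#'
#' @param candidates list of character vectors of feature names (an empty
#'   vector is the intercept-only model).
#' @param data analysis table with outcome column `infected` or `case`.
#' @param link passed to [fit_risk_model()].
#' @return the winning `lipi_risk_model`, with attribute `"candidates"`
#'   giving per-candidate features, AIC and failure messages.
#' @export
select_model_by_aic <- function(candidates, data, link = "auto") {
  stopifnot(is.list(candidates), length(candidates) >= 1L)
  ycol <- if ("infected" %in% names(data)) "infected" else "case"
  fits <- vector("list", length(candidates))
  info <- data.frame(candidate = vapply(candidates, function(f)
    if (length(f) == 0L) "(intercept)" else paste(f, collapse = "+"),
    character(1)), aic = NA_real_, error = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    f <- candidates[[i]]
    rhs <- if (length(f) == 0L) "1"
    else paste(sprintf("`%s`", f), collapse = " + ")
    fml <- stats::as.formula(paste(ycol, "~", rhs))
    fits[[i]] <- tryCatch(fit_risk_model(fml, data, link = link),
                          error = function(e) conditionMessage(e))
    if (inherits(fits[[i]], "lipi_risk_model"))
      info$aic[i] <- fits[[i]]$aic
    else info$error[i] <- fits[[i]]
  }
  ok <- which(!is.na(info$aic))
  if (length(ok) == 0L)
    stop("all candidate models failed:\n",
         paste(sprintf("  %s: %s", info$candidate, info$error),
               collapse = "\n"), call. = FALSE)
  key <- order(info$aic[ok],
               vapply(candidates[ok], length, integer(1)),
               info$candidate[ok])
  best <- fits[[ok[key[1]]]]
  attr(best, "candidates") <- info
  best
}
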