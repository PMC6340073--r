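#' Empirical ROC curve for a dichotomized feature
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' sorted values plus -Inf/+Inf sentinels, so that published rules falling
#' between observed measurements (e.g. "> 8", "< 60.5") are representable.
#' With direction `"greater"` a value is test-positive when it is strictly
#' above the threshold; with `"less"`, strictly below.  When `direction`
#' is not supplied it is auto-detected as the side with the higher event
#' rate (cases' mean above controls' mean implies `"greater"`).
#'
#' @param values numeric feature values, finite.
#' @param labels logical (or 0/1) event indicator, both classes present.
#' @param direction `"greater"`, `"less"`, or `NULL` to auto-detect.
#' @return a `lipi_roc` data.frame of `threshold`, `sens`, `spec` with
#'   attributes `direction`, `n_pos`, `n_neg`.
#' @export
roc_points <- function(values, labels, direction = NULL) {
  labels <- as.logical(labels)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels))
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  if (is.null(direction))
    direction <- if (mean(values[labels]) >= mean(values[!labels]))
      "greater" else "less"
  direction <- match.arg(direction, c("greater", "less"))

  u <- sort(unique(values))
  thr <- if (length(u) > 1L)
    c(-Inf, (utils::head(u, -1) + utils::tail(u, -1)) / 2, Inf)
  else c(-Inf, Inf)
  pos <- values[labels]; neg <- values[!labels]
  m <- length(pos); n <- length(neg)
  # cumulative counts at each distinct value; threshold j sits between
  # u[j] and u[j+1], so counts at <= u[j] give sens/spec in O(n log n)
  k <- length(u)
  cpos <- c(0, cumsum(tabulate(findInterval(pos, u), nbins = k)))
  cneg <- c(0, cumsum(tabulate(findInterval(neg, u), nbins = k)))
  if (length(u) == 1L) { cpos <- cpos[c(1, 2)]; cneg <- cneg[c(1, 2)] }
  if (direction == "greater") {
    sens <- (m - cpos) / m   # strictly above the threshold
    spec <- cneg / n         # at or below
  } else {
    sens <- cpos / m         # strictly below
    spec <- (n - cneg) / n   # at or above
  }
  out <- data.frame(threshold = thr, sens = sens, spec = spec)
  attr(out, "direction") <- direction
  attr(out, "n_pos") <- length(pos)
  attr(out, "n_neg") <- length(neg)
  class(out) <- c("lipi_roc", "data.frame")
  out
}

#' @export
plot.lipi_roc <- function(x, ...) {
  graphics::plot(1 - x$spec, x$sens, type = "s", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "1 - specificity",
                 ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Closest-to-corner dichotomization cutoff
#'
#' Returns the threshold minimizing the squared distance to the perfect
#' (sens = 1, spec = 1) corner, `(1 - sens)^2 + (1 - spec)^2`.  Ties are
#' broken in favour of higher specificity, then of the threshold giving
#' fewer test-positives (the more extreme cut) — the rule is a rule-in
#' test, so among equally good cuts the more specific one wins.  Youden's
#' J (`sens + spec - 1`, maximized) is available for comparison.
#'
#' @param curve a [roc_points()] result.
#' @param criterion `"closest_corner"` (default) or `"youden"`.
#' @param feature optional feature name carried into the result.
#' @return a `lipi_cutoff` list: `feature`, `threshold`, `direction`,
#'   `sens`, `spec`, `criterion`.
#' @export
closest_corner_cutoff <- function(curve,
                                  criterion = c("closest_corner", "youden"),
                                  feature = NA_character_) {
  stopifnot(inherits(curve, "lipi_roc"))
  criterion <- match.arg(criterion)
  crit <- if (criterion == "closest_corner")
    (1 - curve$sens)^2 + (1 - curve$spec)^2
  else -(curve$sens + curve$spec - 1)  # minimized
  n_pos <- attr(curve, "n_pos"); n_neg <- attr(curve, "n_neg")
  positives <- curve$sens * n_pos + (1 - curve$spec) * n_neg
  ord <- order(crit, -curve$spec, positives)
  i <- ord[1]
  structure(list(feature = feature, threshold = curve$threshold[i],
                 direction = attr(curve, "direction"),
                 sens = curve$sens[i], spec = curve$spec[i],
                 criterion = (1 - curve$sens[i])^2 + (1 - curve$spec[i])^2),
            class = "lipi_cutoff")
}

#' @export
print.lipi_cutoff <- function(x, ...) {
  op <- if (x$direction == "greater") ">" else "<"
  cat(sprintf("Cutoff%s: %s %s (sens %.3f, spec %.3f, criterion %.4f)\n",
              if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
              op, format(x$threshold), x$sens, x$spec, x$criterion))
  invisible(x)
}
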