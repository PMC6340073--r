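# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (full enumeration, explicit pair loops) so they share
# no code path with the implementation they check.

# two-sided exact Mann-Whitney p by full enumeration of group assignments
oracle_mw_p <- function(x, y) {
  comb <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(comb), n1)
  ustat <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  U <- apply(idx, 2, function(i) ustat(comb[i], comb[-i]))
  u <- ustat(x, y)
  min(1, 2 * min(mean(U <= u), mean(U >= u)))
}

# AUC by explicit case-control pair counting (ties count one half)
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# minimal closest-to-corner criterion over every candidate threshold,
# recomputing sens/spec by direct counting
oracle_corner_min <- function(values, labels, direction) {
  labels <- as.logical(labels)
  u <- sort(unique(values))
  thr <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  best <- Inf
  for (t in thr) {
    if (direction == "greater") {
      sens <- sum(values[labels] > t) / sum(labels)
      spec <- sum(values[!labels] <= t) / sum(!labels)
    } else {
      sens <- sum(values[labels] < t) / sum(labels)
      spec <- sum(values[!labels] >= t) / sum(!labels)
    }
    best <- min(best, (1 - sens)^2 + (1 - spec)^2)
  }
  best
}

# small deterministic three-patient cohort used by I/O and scoring tests
tiny_cohort <- function() {
  visits <- data.frame(
    patient_id = rep(c("A", "B", "C"), each = 2),
    day = rep(c(0, 90), 3),
    sledai = c(12, 4, 0, 2, 8, 8),
    bilag = c(5, 1, 0, 0, 3, 3),
    prednisone_mg_day = c(30, 7.5, 0, 5, 60, 40),
    drugs = c("cyclophosphamide", "cyclophosphamide", "", "",
              "azathioprine", "azathioprine"),
    th17 = c(11, 12, 3, 2, 9, 8),
    b_cells = c(47, 50, 157, 160, 55, 58),
    tlr2_mfi = c(1500, 1480, 8396, 8100, 1200, 1300),
    stringsAsFactors = FALSE)
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    infected = c(TRUE, FALSE, TRUE),
    infection_day = c(150, NA, 200),
    severe = c(FALSE, NA, TRUE),
    followup_days = 365,
    stringsAsFactors = FALSE)
  lipi_cohort(visits, patients, c("th17", "b_cells", "tlr2_mfi"))
}

strong_effects_config <- function(n = 2000, seed = 1) {
  generator_config(
    n_patients = n, seed = seed,
    effects = c(th17 = 2, b_cells = -2, tlr2_mfi = -1),
    binary_effects = c(cyclophosphamide = 1.5))
}
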