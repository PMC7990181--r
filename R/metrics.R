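#' Concordance index of a risk ranking
#'
#' The censoring-aware ranking score
#' `CI = sum_{i,j} d_i 1(y_j > y_i, eta_j < eta_i) / sum_{i,j} d_i 1(y_j > y_i)`:
#' over all ordered pairs whose first member had an observed event and
#' strictly shorter follow-up, the proportion in which the longer-surviving
#' sample also has the strictly smaller risk score. Ties in either time or
#' score contribute nothing to the numerator (time ties also leave the
#' denominator). `CI = 1` is perfect ranking, `0.5` is chance.
#'
#' @param eta Per-sample risk scores (larger = higher predicted hazard).
#' @param outcomes A `survival_records` table aligned with `eta`.
#' @return Scalar in `[0, 1]`.
#' @export
concordance_index <- function(eta, outcomes) {
  stopifnot(length(eta) == nrow(outcomes))
  y <- outcomes$time; d <- outcomes$event
  num <- 0; den <- 0
  for (i in which(d == 1)) {
    later <- y > y[i]
    den <- den + sum(later)
    num <- num + sum(later & eta < eta[i])
  }
  if (den == 0)
    abort_evorisk("no comparable pairs: concordance index undefined",
                  "evorisk_degenerate_error")
  num / den
}

#' Two-group logrank test
#'
#' The standard one-degree-of-freedom logrank test of the null hypothesis
#' that the two groups share the same survival profile:
#' `z^2 = (sum(O - E))^2 / sum(V)` accumulated over distinct event times,
#' with hypergeometric expectation and variance at each time, referred to
#' a chi-squared distribution with one degree of freedom.
#'
#' @param group Logical or two-level vector assigning each sample to a
#'   group; both groups must be non-empty.
#' @param outcomes A `survival_records` table aligned with `group`.
#' @return List with `z2` (statistic) and `p` (p-value).
#' @export
logrank_test <- function(group, outcomes) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L)
    abort_evorisk("logrank needs exactly two non-empty groups",
                  "evorisk_validation_error")
  y <- outcomes$time; d <- outcomes$event
  if (sum(d) == 0)
    abort_evorisk("no events: logrank test undefined",
                  "evorisk_degenerate_error")
  in1 <- g == 1L
  oe <- 0; v <- 0
  for (t in sort(unique(y[d == 1]))) {
    at_risk <- y >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in1)
    dd <- sum(y == t & d == 1); d1 <- sum(y == t & d == 1 & in1)
    oe <- oe + d1 - dd * n1 / n
    if (n > 1)
      v <- v + dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
  }
  z2 <- if (v > 0) oe^2 / v else 0
  list(z2 = z2, p = stats::pchisq(z2, df = 1L, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival probability after each distinct event time; censored times
#' shrink the risk set without creating steps. With no events the curve is
#' identically 1.
#'
#' @param outcomes A `survival_records` table.
#' @return Data frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `surv` (nonincreasing, in `[0, 1]`).
#' @export
km_curve <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1L)
  y <- outcomes$time; d <- outcomes$event
  times <- sort(unique(y[d == 1]))
  surv <- numeric(length(times))
  n_risk <- integer(length(times)); n_event <- integer(length(times))
  s <- 1
  for (k in seq_along(times)) {
    t <- times[k]
    n_risk[k] <- sum(y >= t)
    n_event[k] <- sum(y == t & d == 1)
    s <- s * (1 - n_event[k] / n_risk[k])
    surv[k] <- s
  }
  structure(data.frame(time = times, n_risk = n_risk, n_event = n_event,
                       surv = surv),
            class = c("km_curve", "data.frame"))
}
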