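#' Median-split hazard ratio of a set of risk scores
#'
#' Samples with held-out risk score strictly above the median are labelled
#' predicted-malignant, the rest predicted-benign (scores exactly at the
#' median go to the benign group). The hazard ratio between the groups is
#' `exp(mean(eta[malignant]) - mean(eta[benign]))` -- the per-group-mean
#' form of the grouped-hazard exponent ratio, adopted so odd-sized cohorts
#' are well-defined (with an exact median split the group-count factor
#' cancels in the downstream fraction ratios). By construction the
#' malignant mean is at least the benign mean, so `HR >= 1` always; a
#' constant score vector yields `HR = 1` and is flagged uninformative.
#'
#' @param eta Numeric vector of (held-out) risk scores, length >= 2.
#' @return List of class `hazard_split`: `hr`, `loghr`, `threshold`
#'   (median), `malignant` (logical per sample), `informative`.
#' @export
hazard_ratio <- function(eta) {
  stopifnot(length(eta) >= 2L)
  med <- stats::median(eta)
  malignant <- eta > med
  if (!any(malignant) || all(malignant)) {
    return(structure(list(hr = 1, loghr = 0, threshold = med,
                          malignant = malignant, informative = FALSE),
                     class = "hazard_split"))
  }
  loghr <- mean(eta[malignant]) - mean(eta[!malignant])
  structure(list(hr = exp(loghr), loghr = loghr, threshold = med,
                 malignant = malignant,
                 informative = loghr > 0),
            class = "hazard_split")
}

replicate_hrs <- function(run) {
  pr <- run$predictions
  vapply(sort(unique(pr$replicate)), function(r) {
    hazard_ratio(pr$eta[pr$replicate == r])$hr
  }, numeric(1L))
}

#' Log-hazard-ratio fraction attribution
#'
#' The headline statistic: the share of explainable progression risk
#' attributable to a feature class. Three two-loop CV runs score the same
#' cohort -- evolutionary features only, evolutionary + driver
#' ("genomic"), and the full evolutionary + driver + clinical set. Per
#' replicate, each run's pooled held-out risk scores give a median-split
#' hazard ratio; HRs are averaged over replicates (arithmetic mean by
#' default) and the fractions are ratios of the log mean-HRs:
#' `fraction(evolutionary) = logHR(evo) / logHR(full)` and
#' `fraction(genomic) = logHR(evo+driver) / logHR(full)`. Values normally
#' fall in `[0, 1]`; above 1 means the extra features actually hurt.
#'
#' @param evolutionary,genomic,full `cv_result` objects from
#'   [two_loop_cv()] runs on the three nested feature sets over the same
#'   cohort. `genomic` may be `NULL` when only the evolutionary fraction
#'   is of interest.
#' @param hr_aggregate How to average replicate HRs before taking logs.
#' @return List of class `fraction_estimate`: `fraction_evolutionary`,
#'   `fraction_genomic`, `hr` (replicate x set matrix), `hr_mean`,
#'   `hr_sd`.
#' @export
fraction_metrics <- function(evolutionary, genomic, full,
                             hr_aggregate = c("arithmetic", "geometric")) {
  hr_aggregate <- match.arg(hr_aggregate)
  runs <- list(evolutionary = evolutionary, genomic = genomic, full = full)
  runs <- runs[!vapply(runs, is.null, logical(1L))]
  hr <- vapply(runs, replicate_hrs,
               numeric(length(unique(full$predictions$replicate))))
  hr <- matrix(hr, ncol = length(runs),
               dimnames = list(NULL, names(runs)))
  agg <- if (hr_aggregate == "arithmetic") colMeans(hr) else
    exp(colMeans(log(hr)))
  if (log(agg[["full"]]) == 0)
    abort_evorisk("full-model log hazard ratio is zero: fraction undefined",
                  "evorisk_degenerate_error")
  structure(list(
    fraction_evolutionary = log(agg[["evolutionary"]]) / log(agg[["full"]]),
    fraction_genomic = if ("genomic" %in% names(runs))
      log(agg[["genomic"]]) / log(agg[["full"]]) else NA_real_,
    hr = hr, hr_mean = agg, hr_sd = apply(hr, 2L, stats::sd),
    hr_aggregate = hr_aggregate),
    class = "fraction_estimate")
}

#' Cohort stratification report
#'
#' Splits scored samples at the median risk score, builds the two
#' Kaplan-Meier curves and runs the logrank test between the
#' predicted-malignant and predicted-benign cohorts.
#'
#' @param eta Held-out risk scores aligned with `outcomes`.
#' @param outcomes A `survival_records` table.
#' @return List of class `stratification_report`: `split`
#'   (`hazard_split`), `km` (named list of two `km_curve`s), `logrank`,
#'   and `table` (machine-readable per-sample assignment).
#' @export
stratification_report <- function(eta, outcomes) {
  stopifnot(length(eta) == nrow(outcomes))
  split <- hazard_ratio(eta)
  if (!any(split$malignant) || all(split$malignant))
    abort_evorisk("degenerate median split: a group is empty",
                  "evorisk_degenerate_error")
  km <- list(
    malignant = km_curve(outcomes[split$malignant, , drop = FALSE]),
    benign = km_curve(outcomes[!split$malignant, , drop = FALSE]))
  lr <- logrank_test(split$malignant, outcomes)
  structure(list(split = split, km = km, logrank = lr,
                 table = data.frame(sample = outcomes$sample, eta = eta,
                                    group = ifelse(split$malignant,
                                                   "malignant", "benign"),
                                    stringsAsFactors = FALSE)),
            class = "stratification_report")
}

#' @export
plot.stratification_report <- function(x, main = "Median-split survival",
                                       ...) {
  step_xy <- function(km, tmax) {
    list(x = c(0, rep(km$time, each = 2L), tmax),
         y = c(1, 1, rep(km$surv, each = 2L)))
  }
  tmax <- max(c(x$km$malignant$time, x$km$benign$time, 0))
  m <- step_xy(x$km$malignant, tmax); b <- step_xy(x$km$benign, tmax)
  graphics::plot(m$x, m$y, type = "l", col = "firebrick", ylim = c(0, 1),
                 xlab = "time (months)", ylab = "survival probability",
                 main = main, ...)
  graphics::lines(b$x, b$y, col = "steelblue")
  graphics::legend("bottomleft", bty = "n", lwd = 1,
                   col = c("firebrick", "steelblue"),
                   legend = c("predicted malignant", "predicted benign"))
  graphics::mtext(sprintf("logrank p = %.3g", x$logrank$p), side = 3,
                  line = 0, cex = 0.8)
  invisible(x)
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf("fraction(evolutionary) = %.3f\nfraction(genomic)      = %.3f\n",
              x$fraction_evolutionary, x$fraction_genomic))
  cat("mean HR per feature set:\n")
  print(round(x$hr_mean, 3))
  invisible(x)
}
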