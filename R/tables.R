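#' Read censored outcome records
#'
#' Outcome tables are TSV files with a header and, per endpoint, a time and
#' an event column named `<endpoint>_time` / `<endpoint>_event` (e.g.
#' `os_time`, `os_event`). Times are follow-up times `y = min(T, C)` in
#' months; events are `1` if the event (death for OS, recurrence for DFS)
#' was observed at `y`, `0` if censored.
#'
#' @param path TSV path.
#' @param endpoint `"os"` or `"dfs"` (case-insensitive).
#' @return Data frame of class `survival_records` with columns `sample`,
#'   `time`, `event`.
#' @export
read_outcomes <- function(path, endpoint = "os") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  endpoint <- tolower(endpoint)
  tc <- paste0(endpoint, "_time"); ec <- paste0(endpoint, "_event")
  if (!all(c("sample", tc, ec) %in% names(tab)))
    abort_evorisk(sprintf("outcome table lacks columns sample/%s/%s", tc, ec),
                  "evorisk_parse_error")
  survival_records(tab$sample, tab[[tc]], tab[[ec]])
}

#' Construct validated survival records
#'
#' @param sample Sample identifiers.
#' @param time Follow-up times, `> 0`.
#' @param event Event indicators in `{0, 1}`.
#' @return Data frame of class `survival_records`.
#' @export
survival_records <- function(sample, time, event) {
  time <- as.numeric(time); event <- as.numeric(event)
  if (any(is.na(time)) || any(time <= 0))
    abort_evorisk("follow-up times must be positive",
                  "evorisk_validation_error")
  if (any(is.na(event)) || !all(event %in% c(0, 1)))
    abort_evorisk("event indicators must be 0 or 1",
                  "evorisk_validation_error")
  structure(data.frame(sample = as.character(sample), time = time,
                       event = event, stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

#' Write an outcome table
#' @param outcomes Named list of `survival_records`, one per endpoint (names
#'   become column prefixes), all covering the same samples.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  stopifnot(length(outcomes) >= 1L)
  base <- outcomes[[1L]]$sample
  out <- data.frame(sample = base, stringsAsFactors = FALSE)
  for (ep in names(outcomes)) {
    rec <- outcomes[[ep]]
    m <- match(base, rec$sample)
    out[[paste0(ep, "_time")]] <- rec$time[m]
    out[[paste0(ep, "_event")]] <- rec$event[m]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' Clinical tables are TSV files with a `sample` column plus one column per
#' attribute. Attribute kinds (`binary`, `categorical`, `continuous`) are
#' declared on a leading comment line of the form
#' `#kind<TAB>attr=binary<TAB>attr2=continuous...`; when absent they are
#' inferred (numeric -> continuous, two distinct values -> binary, else
#' categorical).
#'
#' @param path TSV path.
#' @return A list of class `clinical_table` with elements `data` (data
#'   frame keyed by `sample`) and `kinds` (named character vector).
#' @export
read_clinical <- function(path) {
  first <- readLines(path, n = 1L)
  kinds <- NULL
  skip <- 0L
  if (startsWith(first, "#kind")) {
    skip <- 1L
    decl <- strsplit(sub("^#kind\\t?", "", first), "\t", fixed = TRUE)[[1L]]
    kv <- strsplit(decl, "=", fixed = TRUE)
    kinds <- stats::setNames(vapply(kv, `[`, "", 2L),
                             vapply(kv, `[`, "", 1L))
  }
  tab <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"sample" %in% names(tab))
    abort_evorisk("clinical table needs a 'sample' column",
                  "evorisk_parse_error")
  clinical_table(tab, kinds = kinds)
}

#' Construct a validated clinical table
#' @param data Data frame with a `sample` column and one column per
#'   attribute.
#' @param kinds Optional named character vector of attribute kinds; missing
#'   kinds are inferred.
#' @return A `clinical_table`.
#' @export
clinical_table <- function(data, kinds = NULL) {
  attrs <- setdiff(names(data), "sample")
  infer <- function(a) {
    x <- data[[a]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2L) "continuous"
    else if (length(unique(stats::na.omit(x))) <= 2L) "binary"
    else "categorical"
  }
  full <- stats::setNames(vapply(attrs, infer, character(1L)), attrs)
  if (!is.null(kinds)) {
    if (!all(kinds %in% c("binary", "categorical", "continuous")))
      abort_evorisk("unknown clinical kind label", "evorisk_config_error")
    full[names(kinds)] <- kinds
  }
  if (!all(attrs %in% names(full)))
    abort_evorisk("kinds must cover all attributes", "evorisk_config_error")
  structure(list(data = data, kinds = full[attrs]), class = "clinical_table")
}

#' @rdname read_clinical
#' @param tab A `clinical_table`.
#' @export
write_clinical <- function(tab, path) {
  decl <- paste0("#kind\t",
                 paste(names(tab$kinds), tab$kinds, sep = "=", collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(decl, con)
  utils::write.table(tab$data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Joined cohort of samples present in every source
#'
#' The pipeline's cohort is the sorted intersection of the sample sets seen
#' by the feature sources and outcome table; samples present in one source
#' but not another are reported and dropped.
#'
#' @param ... Character vectors of sample ids.
#' @param quiet Suppress the dropped-sample message.
#' @return Sorted character vector of shared sample ids.
#' @export
joined_cohort <- function(..., quiet = FALSE) {
  sets <- list(...)
  shared <- Reduce(intersect, sets)
  dropped <- length(unique(unlist(sets))) - length(shared)
  if (dropped > 0L && !quiet)
    message(sprintf("dropping %d sample(s) absent from at least one source",
                    dropped))
  sort(shared)
}
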