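#' Construct a tagged feature matrix
#'
#' The model-ready container: a samples-by-features numeric matrix in which
#' every feature carries a class tag (`evolutionary`, `driver` or
#' `clinical`) used downstream to assemble feature-set runs.
#'
#' @param x Numeric matrix with sample row names and feature column names.
#' @param classes Named character vector, one tag per feature.
#' @return A list of class `feature_matrix` with elements `x` and
#'   `classes`.
#' @export
feature_matrix <- function(x, classes) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    abort_evorisk("feature matrix needs sample and feature names",
                  "evorisk_validation_error")
  if (anyDuplicated(colnames(x)))
    abort_evorisk(sprintf("duplicate feature name: %s",
                          colnames(x)[duplicated(colnames(x))][1L]),
                  "evorisk_validation_error")
  if (!setequal(names(classes), colnames(x)))
    abort_evorisk("every feature needs exactly one class tag",
                  "evorisk_validation_error")
  structure(list(x = x, classes = classes[colnames(x)]),
            class = "feature_matrix")
}

#' Read a driver catalog
#'
#' Driver catalogs are BED-like TSV files with a header and columns
#' `chrom`, `start`, `end`, `name` (1-based inclusive coordinates). A
#' driver may span several intervals (repeated name).
#'
#' @param path TSV path.
#' @return Data frame of class `driver_catalog`.
#' @export
read_driver_catalog <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  driver_catalog(tab)
}

#' @rdname read_driver_catalog
#' @param tab Data frame with columns `chrom`, `start`, `end`, `name`.
#' @export
driver_catalog <- function(tab) {
  if (!all(c("chrom", "start", "end", "name") %in% names(tab)))
    abort_evorisk("driver catalog needs chrom/start/end/name",
                  "evorisk_parse_error")
  if (any(tab$end < tab$start))
    abort_evorisk("driver interval with end < start",
                  "evorisk_validation_error")
  structure(tab, class = c("driver_catalog", "data.frame"))
}

#' Built-in driver catalog for the toy genome
#'
#' Twenty synthetic driver intervals laid out deterministically on the toy
#' genome; a stand-in for user-supplied IntOGen/COSMIC-derived lists.
#'
#' @param n_drivers Number of intervals.
#' @param genome Genome whose contigs the intervals live on.
#' @param width Interval width in bp.
#' @param seed Placement seed.
#' @return A `driver_catalog`.
#' @export
toy_driver_catalog <- function(n_drivers = 20L, genome = toy_genome(),
                               width = 20000L, seed = 99L) {
  with_seed(seed, {
    chrom <- sample(names(genome), n_drivers, replace = TRUE)
    start <- vapply(chrom, function(ch) {
      sample.int(nchar(genome[[ch]]) - width, 1L)
    }, integer(1L))
    driver_catalog(data.frame(
      chrom = chrom, start = start, end = start + width - 1L,
      name = sprintf("DRV%02d", seq_len(n_drivers)),
      stringsAsFactors = FALSE))
  })
}

# Does a variant record hit an interval? SNVs/indels by position; CNAs if
# their span intersects; SVs if either breakpoint falls inside.
hits_interval <- function(v, chrom, start, end) {
  on_chrom <- v$chrom == chrom
  pointhit <- on_chrom & v$pos >= start & v$pos <= end
  hit <- pointhit
  cna <- v$vclass == "CNA" & on_chrom
  hit[cna] <- v$pos[cna] <= end & v$cna_end[cna] >= start
  sv <- v$vclass == "SV"
  if (any(sv & !hit)) {
    mate <- strsplit(v$sv_mate[sv], ":", fixed = TRUE)
    m_chrom <- vapply(mate, `[`, "", 1L)
    m_pos <- suppressWarnings(as.integer(vapply(mate, `[`, "", 2L)))
    mate_hit <- !is.na(m_pos) & m_chrom == chrom & m_pos >= start &
      m_pos <= end
    hit[sv] <- hit[sv] | mate_hit
  }
  hit
}

#' Driver mutation-rate features
#'
#' One feature per driver: the number of somatic events of any class (SNV,
#' indel, CNA, SV) overlapping the driver's interval(s), divided by the
#' assumed edge duration. CNAs count if their span intersects the
#' interval; SVs if either breakpoint does. A driver hit by several events
#' in a sample counts each event.
#'
#' @param variants_by_sample Named list of `evorisk_variants`.
#' @param catalog A `driver_catalog` sharing the genome build of the
#'   variant coordinates.
#' @param edge_years Assumed edge duration in years.
#' @param contigs Optional character vector of valid contig names; variants
#'   on other contigs are a hard error.
#' @return A [feature_matrix()] tagged `driver`, columns `drv_<name>`.
#' @export
driver_features <- function(variants_by_sample, catalog, edge_years = 10,
                            contigs = NULL) {
  names_u <- unique(catalog$name)
  x <- vapply(variants_by_sample, function(v) {
    if (!is.null(contigs)) {
      unknown <- setdiff(unique(v$chrom), contigs)
      if (length(unknown))
        abort_evorisk(paste0("variant contigs not in reference: ",
                             paste(unknown, collapse = ", ")),
                      "evorisk_contig_error")
    }
    vapply(names_u, function(nm) {
      iv <- catalog[catalog$name == nm, , drop = FALSE]
      hit <- Reduce(`|`, lapply(seq_len(nrow(iv)), function(k) {
        hits_interval(v, iv$chrom[k], iv$start[k], iv$end[k])
      }))
      sum(hit) / edge_years
    }, numeric(1L))
  }, numeric(length(names_u)))
  x <- if (is.matrix(x)) t(x) else matrix(x, ncol = 1L)
  colnames(x) <- paste0("drv_", names_u)
  rownames(x) <- names(variants_by_sample)
  feature_matrix(x, stats::setNames(rep("driver", ncol(x)), colnames(x)))
}

#' Encode clinical covariates into model-ready columns
#'
#' Binary attributes become a single 0/1 column; categorical attributes
#' with k levels become k indicator columns named `attr|level` (no
#' reference level is dropped -- each level is a feature in its own right,
#' and the induced collinearity is handled by the pruning stage);
#' continuous attributes pass through. Missing values are imputed with the
#' observed mode (binary/categorical) or median (continuous) and the
#' per-attribute missingness count is reported via a message.
#'
#' @param tab A `clinical_table`.
#' @param quiet Suppress missingness messages.
#' @return A [feature_matrix()] tagged `clinical`.
#' @export
encode_clinical <- function(tab, quiet = FALSE) {
  data <- tab$data
  ids <- as.character(data$sample)
  cols <- list()
  for (a in names(tab$kinds)) {
    x <- data[[a]]
    n_miss <- sum(is.na(x))
    if (n_miss > 0L && !quiet)
      message(sprintf("clinical attribute '%s': imputing %d missing value(s)",
                      a, n_miss))
    kind <- tab$kinds[[a]]
    if (kind == "continuous") {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      cols[[a]] <- as.numeric(x)
    } else {
      mode_lvl <- names(sort(table(x), decreasing = TRUE))[1L]
      x[is.na(x)] <- mode_lvl
      if (kind == "binary") {
        lv <- sort(unique(as.character(x)))
        if (length(lv) > 2L)
          abort_evorisk(sprintf("binary attribute '%s' has >2 levels", a),
                        "evorisk_config_error")
        cols[[a]] <- as.numeric(as.character(x) == lv[length(lv)])
      } else if (kind == "categorical") {
        for (lv in sort(unique(as.character(x))))
          cols[[paste0(a, "|", lv)]] <- as.numeric(as.character(x) == lv)
      } else {
        abort_evorisk(sprintf("unknown kind '%s'", kind),
                      "evorisk_config_error")
      }
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- ids
  feature_matrix(x, stats::setNames(rep("clinical", ncol(x)), colnames(x)))
}

#' Assemble feature blocks into one aligned design
#'
#' Inner-joins any number of [feature_matrix()] blocks and an outcome table
#' on sample id (the joined cohort is the sorted intersection; dropped
#' samples are reported), checks for duplicate feature names across blocks,
#' and returns the aligned pair the survival machinery consumes. The
#' result contains no missing values.
#'
#' @param ... `feature_matrix` blocks.
#' @param outcomes A `survival_records` table.
#' @param quiet Suppress the dropped-sample message.
#' @return List with elements `features` (a `feature_matrix`) and
#'   `outcomes` (reordered `survival_records`).
#' @export
assemble_matrix <- function(..., outcomes, quiet = FALSE) {
  blocks <- list(...)
  stopifnot(length(blocks) >= 1L)
  all_names <- unlist(lapply(blocks, function(b) colnames(b$x)))
  if (anyDuplicated(all_names))
    abort_evorisk(sprintf("duplicate feature name across blocks: %s",
                          all_names[duplicated(all_names)][1L]),
                  "evorisk_validation_error")
  ids <- do.call(joined_cohort, c(lapply(blocks, function(b) rownames(b$x)),
                                  list(outcomes$sample), list(quiet = quiet)))
  if (!length(ids))
    abort_evorisk("no samples shared across feature blocks and outcomes",
                  "evorisk_validation_error")
  x <- do.call(cbind, lapply(blocks, function(b) b$x[ids, , drop = FALSE]))
  if (anyNA(x))
    abort_evorisk("assembled matrix contains missing values",
                  "evorisk_validation_error")
  classes <- do.call(c, lapply(blocks, function(b) b$classes))
  list(features = feature_matrix(x, classes),
       outcomes = outcomes[match(ids, outcomes$sample), , drop = FALSE])
}
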