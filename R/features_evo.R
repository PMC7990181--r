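PYRIMIDINES <- c("C", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Enumerate the collapsed substitution classes
#'
#' Point substitutions are strand-symmetric: a `G>T` call on one strand is a
#' `C>A` on the other, so the 12 ordered base substitutions collapse onto
#' the 6 pyrimidine-centered classes used in mutational-signature analysis.
#'
#' @return Character vector of the 6 classes, `C>A` ... `T>G`.
#' @export
substitution_classes <- function() {
  sort(unlist(lapply(PYRIMIDINES, function(r) {
    paste0(r, ">", setdiff(BASES, r))
  })))
}

#' Enumerate the trinucleotide substitution classes
#'
#' Each class has the form `N_l[N_x>N_y]N_r`: a collapsed substitution plus
#' its immediate 5' and 3' context, giving 4 x 6 x 4 = 96 classes.
#'
#' @return Character vector of the 96 classes.
#' @export
trinucleotide_classes <- function() {
  grid <- expand.grid(l = BASES, s = substitution_classes(), r = BASES,
                      stringsAsFactors = FALSE)
  sort(paste0(grid$l, "[", grid$s, "]", grid$r))
}

#' Collapse a substitution onto its pyrimidine-centered class
#'
#' Purine-centered substitutions are mapped to their reverse-complement
#' equivalent (`G>T` to `C>A`, `A>G` to `T>C`, ...); pyrimidine-centered
#' ones are returned unchanged. Vectorized.
#'
#' @param ref,alt Single bases in `A/C/G/T`, `ref != alt`.
#' @return Character vector of classes from [substitution_classes()].
#' @export
#' @examples
#' collapse_substitution("G", "T") # "C>A"
collapse_substitution <- function(ref, alt) {
  if (!all(ref %in% BASES) || !all(alt %in% BASES) || any(ref == alt))
    abort_evorisk("ref/alt must be distinct single bases in ACGT",
                  "evorisk_validation_error")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, COMPLEMENT[ref], ref)
  a <- ifelse(pur, COMPLEMENT[alt], alt)
  paste0(r, ">", a)
}

#' Classify an SNV into its trinucleotide class
#'
#' The context is the 3-mer centered on the mutated base. When the center
#' is a purine the whole trinucleotide and the substitution are
#' reverse-complemented before classification, so the result is always one
#' of the 96 pyrimidine-centered classes. Contexts containing `N` are
#' ambiguous and yield `NA` (the variant is excluded from the 96 counts but
#' still contributes to the total SNV rate).
#'
#' @param context 3-character string whose center equals `ref`.
#' @param ref,alt Single bases, `ref != alt`.
#' @return Class string, or `NA` for ambiguous context. Vectorized.
#' @export
#' @examples
#' trinucleotide_class("ACA", "C", "T") # "A[C>T]A"
#' trinucleotide_class("TGA", "G", "A") # "T[C>T]A"
trinucleotide_class <- function(context, ref, alt) {
  if (any(nchar(context[!is.na(context)]) != 3L))
    abort_evorisk("context must be a 3-mer", "evorisk_validation_error")
  center <- substr(context, 2L, 2L)
  if (!all(is.na(context) | center == ref))
    abort_evorisk("context center must equal ref", "evorisk_validation_error")
  out <- rep(NA_character_, length(context))
  ok <- !is.na(context) & !grepl("N", context, fixed = TRUE)
  if (!any(ok)) return(out)
  ctx <- context[ok]; r <- ref[ok]; a <- alt[ok]
  pur <- r %in% c("A", "G")
  ctx[pur] <- revcomp(ctx[pur])
  cls <- collapse_substitution(r, a)
  out[ok] <- paste0(substr(ctx, 1L, 1L), "[", cls, "]", substr(ctx, 3L, 3L))
  out
}

#' Cumulative evolutionary features of one sample
#'
#' Treats all somatic events as acquired on a single normal-to-tumor edge
#' (the degenerate two-node "cumulative" evolutionary model) and converts
#' counts into per-year rates by dividing by the assumed edge duration
#' (default ten years from first ancestral tumor cell to sequencing; the
#' scale is arbitrary and cancels in the downstream regression). Produces
#' the total SNV rate, the 6 collapsed substitution-class rates, the 96
#' trinucleotide-class rates, the indel rate, CNA rates split by direction
#' (`amp`/`del`) and size (above vs at-or-below 500,000 nt), and the SV
#' rate.
#'
#' @param variants An `evorisk_variants` set for one sample.
#' @param genome Reference genome (named character vector) for context
#'   lookup.
#' @param snp_mask Optional character vector of `"chrom:pos"` germline SNP
#'   sites to screen out before counting.
#' @param edge_years Assumed edge duration in years.
#' @return Named numeric vector of nonnegative rates.
#' @export
cumulative_features <- function(variants, genome, snp_mask = NULL,
                                edge_years = 10) {
  stopifnot(edge_years > 0)
  v <- validate_variants(variants)
  if (!is.null(snp_mask) && nrow(v)) {
    v <- v[!paste0(v$chrom, ":", v$pos) %in% snp_mask, , drop = FALSE]
  }
  sub6 <- substitution_classes()
  tri96 <- trinucleotide_classes()
  feats <- c(snv_rate = 0,
             stats::setNames(numeric(6L), sub6),
             stats::setNames(numeric(96L), tri96),
             indel_rate = 0, cna_rate = 0, cna_amp_rate = 0,
             cna_del_rate = 0, cna_lg_rate = 0, cna_sm_rate = 0, sv_rate = 0)
  if (nrow(v) == 0L) return(feats)
  unknown <- setdiff(unique(v$chrom), names(genome))
  if (length(unknown))
    abort_evorisk(paste0("variant contigs not in reference: ",
                         paste(unknown, collapse = ", ")),
                  "evorisk_contig_error")
  snv <- v[v$vclass == "SNV", , drop = FALSE]
  feats["snv_rate"] <- nrow(snv) / edge_years
  if (nrow(snv)) {
    ctx <- fetch_context_safe(genome, snv$chrom, snv$pos)
    # a reference mismatch makes the context unresolvable, not an error:
    # the variant still counts toward the total SNV rate
    ctx[!is.na(ctx) & substr(ctx, 2L, 2L) != snv$ref] <- NA_character_
    cls <- rep(NA_character_, nrow(snv))
    ok <- !is.na(ctx)
    cls[ok] <- trinucleotide_class(ctx[ok], snv$ref[ok], snv$alt[ok])
    resolved <- !is.na(cls)
    tri_tab <- table(factor(cls[resolved], levels = tri96))
    feats[tri96] <- as.numeric(tri_tab) / edge_years
    sub_cls <- collapse_substitution(snv$ref[resolved], snv$alt[resolved])
    feats[sub6] <- as.numeric(table(factor(sub_cls, levels = sub6))) /
      edge_years
  }
  feats["indel_rate"] <- sum(v$vclass == "INDEL") / edge_years
  cna <- v[v$vclass == "CNA", , drop = FALSE]
  if (nrow(cna)) {
    len <- cna_length(cna)
    feats["cna_rate"] <- nrow(cna) / edge_years
    feats["cna_amp_rate"] <- sum(cna$cna_dir == "amp") / edge_years
    feats["cna_del_rate"] <- sum(cna$cna_dir == "del") / edge_years
    feats["cna_lg_rate"] <- sum(len > 500000L) / edge_years
    feats["cna_sm_rate"] <- sum(len <= 500000L) / edge_years
  }
  feats["sv_rate"] <- sum(v$vclass == "SV") / edge_years
  feats
}

#' Phylogenetic evolutionary features of one clone tree
#'
#' Tree summary statistics in mutation-count units: `num_clone` counts the
#' tumor clones (non-root nodes), each edge's length is the total number of
#' somatic events acquired on it (SNV + indel + CNA + SV), `height` is the
#' maximum root-to-leaf path length, `branch_mean` the average edge length,
#' and `branch_mean_sv` the average edge length counting SVs only.
#'
#' @param tree A `clone_tree`.
#' @return Named numeric vector `num_clone`, `height`, `branch_mean`,
#'   `branch_mean_sv`.
#' @export
phylo_features <- function(tree) {
  validate_clone_tree(tree)
  children <- setdiff(tree$nodes, tree$root)
  if (!length(children))
    return(c(num_clone = 0, height = 0, branch_mean = 0, branch_mean_sv = 0))
  ec <- tree$edge_counts[children, MUT_CLASSES, drop = FALSE]
  elen <- rowSums(ec)
  depth <- vapply(children, function(nd) sum(elen[path_to_root(tree, nd)]),
                  numeric(1L))
  c(num_clone = length(children),
    height = max(depth),
    branch_mean = mean(elen),
    branch_mean_sv = mean(ec[, "sv"]))
}

#' Extract the evolutionary feature block for a cohort
#'
#' Applies [cumulative_features()] and [phylo_features()] to every sample
#' and stacks the results into a samples-by-features matrix tagged with the
#' `evolutionary` class.
#'
#' @param variants_by_sample Named list of `evorisk_variants`.
#' @param genome Reference genome.
#' @param trees Optional named list of `clone_tree`s (same names); when
#'   `NULL` the phylogenetic block is omitted.
#' @param trinucleotide Include the 96 trinucleotide rates? Disabling them
#'   gives the compact ~15-column evolutionary block used in scaled-down
#'   experiments.
#' @inheritParams cumulative_features
#' @return A [feature_matrix()].
#' @export
evolutionary_features <- function(variants_by_sample, genome, trees = NULL,
                                  snp_mask = NULL, edge_years = 10,
                                  trinucleotide = TRUE) {
  rows <- lapply(names(variants_by_sample), function(id) {
    f <- cumulative_features(variants_by_sample[[id]], genome,
                             snp_mask = snp_mask, edge_years = edge_years)
    if (!trinucleotide) f <- f[setdiff(names(f), trinucleotide_classes())]
    if (!is.null(trees)) f <- c(f, phylo_features(trees[[id]]))
    f
  })
  x <- do.call(rbind, rows)
  rownames(x) <- names(variants_by_sample)
  feature_matrix(x, classes = stats::setNames(
    rep("evolutionary", ncol(x)), colnames(x)))
}
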