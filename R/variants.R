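#' Construct a validated set of somatic variant records
#'
#' A variant set is the in-memory form of one sample's somatic calls: SNVs,
#' indels, copy-number alterations (CNAs) and structural variants (SVs).
#' It is stored as a data frame with one row per event and carries the
#' class-specific attributes each event type needs.
#'
#' @param chrom Character vector of contig names.
#' @param pos 1-based positions (integer-like, `>= 1`).
#' @param ref,alt Allele strings. SNVs must have single-base `ref`/`alt` in
#'   `A/C/G/T` with `ref != alt`; CNAs use the symbolic ALT `<DUP>`/`<DEL>`;
#'   SVs use breakend notation or symbolic tags.
#' @param vclass One of `"SNV"`, `"INDEL"`, `"CNA"`, `"SV"` per record.
#' @param vaf Variant allele fraction in `[0, 1]`; `NA` allowed (the rate
#'   features in this package count events, they do not weight by VAF).
#' @param cna_end 1-based inclusive CNA end (`NA` for non-CNA records).
#' @param cna_dir `"amp"` or `"del"` for CNAs, `NA` otherwise.
#' @param sv_mate Breakpoint partner locus `"chrom:pos"` for SVs, `NA`
#'   otherwise.
#'
#' @return A `data.frame` of class `evorisk_variants`.
#' @export
#' @examples
#' variant_set(chrom = "chr1", pos = 100, ref = "C", alt = "A",
#'             vclass = "SNV", vaf = 0.4)
variant_set <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        vclass = character(), vaf = NA_real_,
                        cna_end = NA_integer_, cna_dir = NA_character_,
                        sv_mate = NA_character_) {
  n <- length(chrom)
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  vclass = as.character(vclass),
                  vaf = rep_len(as.numeric(vaf), n),
                  cna_end = rep_len(as.integer(cna_end), n),
                  cna_dir = rep_len(as.character(cna_dir), n),
                  sv_mate = rep_len(as.character(sv_mate), n),
                  stringsAsFactors = FALSE)
  class(v) <- c("evorisk_variants", "data.frame")
  validate_variants(v)
}

#' Validate variant-set invariants
#'
#' Checks positions, VAF range, SNV allele alphabet, and CNA end/direction
#' consistency; called by every reader and by [variant_set()].
#'
#' @param v An `evorisk_variants` data frame.
#' @return `v`, invisibly unchanged, or an error of class
#'   `evorisk_validation_error`.
#' @export
validate_variants <- function(v) {
  if (nrow(v) == 0L) return(v)
  if (any(is.na(v$pos)) || any(v$pos < 1L))
    abort_evorisk("variant positions must be 1-based (pos >= 1)",
                  "evorisk_validation_error")
  bad_vaf <- !is.na(v$vaf) & (v$vaf < 0 | v$vaf > 1)
  if (any(bad_vaf))
    abort_evorisk("VAF outside [0, 1]", "evorisk_validation_error")
  if (!all(v$vclass %in% c("SNV", "INDEL", "CNA", "SV")))
    abort_evorisk("vclass must be one of SNV/INDEL/CNA/SV",
                  "evorisk_validation_error")
  snv <- v$vclass == "SNV"
  if (any(snv)) {
    ok <- v$ref[snv] %in% BASES & v$alt[snv] %in% BASES &
      v$ref[snv] != v$alt[snv]
    if (!all(ok))
      abort_evorisk(
        sprintf("SNV record %d: ref/alt must be distinct single bases in ACGT",
                which(snv)[which(!ok)[1L]]),
        "evorisk_validation_error")
  }
  cna <- v$vclass == "CNA"
  if (any(cna)) {
    if (any(is.na(v$cna_end[cna])) || any(v$cna_end[cna] < v$pos[cna]))
      abort_evorisk("CNA records need cna_end >= pos",
                    "evorisk_validation_error")
    if (any(is.na(v$cna_dir[cna])) || !all(v$cna_dir[cna] %in% c("amp", "del")))
      abort_evorisk("CNA records need cna_dir in {amp, del}",
                    "evorisk_validation_error")
  }
  v
}

# Length of a CNA in nucleotides, 1-based inclusive coordinates.
cna_length <- function(v) {
  ifelse(v$vclass == "CNA", v$cna_end - v$pos + 1L, NA_integer_)
}
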