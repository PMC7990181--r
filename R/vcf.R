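VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant described in this record\">",
  "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
  "##FORMAT=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">")

#' Write somatic variant records to a VCF 4.2 file
#'
#' Emits the package's VCF dialect: SNVs and indels as literal-allele
#' records, CNAs as symbolic `<DUP>`/`<DEL>` ALTs with an `END` INFO key,
#' SVs as breakend (BND) records whose ALT encodes the partner locus.
#' VAF is written as a per-sample FORMAT field. Coordinates are 1-based
#' inclusive throughout; `write_vcf()` and [read_vcf()] are mutually
#' inverse on valid variant sets.
#'
#' @param v An `evorisk_variants` data frame (see [variant_set()]).
#' @param path Output path.
#' @param sample Sample name for the genotype column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, sample = "TUMOR") {
  validate_variants(v)
  fmt_vaf <- ifelse(is.na(v$vaf), ".", sprintf("%.10g", v$vaf))
  ref <- v$ref
  alt <- v$alt
  info <- rep(".", nrow(v))
  cna <- v$vclass == "CNA"
  if (any(cna)) {
    alt[cna] <- ifelse(v$cna_dir[cna] == "amp", "<DUP>", "<DEL>")
    ref[cna] <- ifelse(ref[cna] %in% BASES, ref[cna], "N")
    info[cna] <- sprintf("END=%d;SVTYPE=%s", v$cna_end[cna],
                         ifelse(v$cna_dir[cna] == "amp", "DUP", "DEL"))
  }
  sv <- v$vclass == "SV"
  if (any(sv)) {
    ref[sv] <- ifelse(ref[sv] %in% BASES, ref[sv], "N")
    alt[sv] <- sprintf("%s[%s[", ref[sv], v$sv_mate[sv])
    info[sv] <- "SVTYPE=BND"
  }
  lines <- c(
    VCF_HEADER,
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample), collapse = "\t")),
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tVAF\t%s",
            v$chrom, v$pos, ref, alt, info, fmt_vaf))
  writeLines(lines, path)
  invisible(path)
}

#' Read somatic variant records from a VCF 4.x file
#'
#' Parsing is delegated to `VariantAnnotation::readVcf()`; records are then
#' classified and validated into an `evorisk_variants` set. Classification:
#' symbolic `<DUP>`/`<DEL>` ALT with an `END` key is a CNA; breakend or
#' other symbolic ALTs (`<INV>`, `<TRA>`, `<BND>`) are SVs; single-base
#' REF/ALT is an SNV; remaining literal-allele records are indels. VAF is
#' taken from the per-sample `VAF` FORMAT field when present, else from an
#' `VAF` INFO field, else `NA`.
#'
#' @param path Path to a VCF file.
#' @param sample Sample column to read genotype fields from; defaults to
#'   the first sample in the file.
#' @return An `evorisk_variants` data frame, 1-based coordinates as in VCF.
#' @export
read_vcf <- function(path, sample = NULL) {
  check_vcf_lines(path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) abort_evorisk(
      sprintf("failed to parse VCF '%s': %s", path, conditionMessage(e)),
      "evorisk_parse_error"))
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(as(VariantAnnotation::alt(vcf), "CharacterList"),
                function(a) if (length(a)) as.character(a[[1L]]) else ".",
                character(1L))
  info <- VariantAnnotation::info(vcf)
  end <- if ("END" %in% names(info)) suppressWarnings(as.integer(info$END))
         else rep(NA_integer_, n)
  vaf <- rep(NA_real_, n)
  gen <- VariantAnnotation::geno(vcf)
  if ("VAF" %in% names(gen)) {
    gm <- gen$VAF
    col <- if (is.null(sample)) 1L else {
      if (!sample %in% colnames(gm))
        abort_evorisk(sprintf("sample '%s' not in VCF", sample),
                      "evorisk_parse_error")
      sample
    }
    vaf <- suppressWarnings(as.numeric(gm[, col]))
  } else if ("VAF" %in% names(info)) {
    vaf <- suppressWarnings(as.numeric(info$VAF))
  }

  is_dup <- alt == "<DUP>"
  is_del <- alt == "<DEL>"
  is_bnd <- grepl("[][]", alt)
  is_sym_sv <- alt %in% c("<INV>", "<TRA>", "<BND>")
  vclass <- ifelse(is_dup | is_del, "CNA",
            ifelse(is_bnd | is_sym_sv, "SV",
            ifelse(nchar(ref) == 1L & nchar(alt) == 1L &
                   ref %in% BASES & alt %in% BASES, "SNV", "INDEL")))
  sv_mate <- rep(NA_character_, n)
  if (any(is_bnd))
    sv_mate[is_bnd] <- sub("^.*[][]([^][]+)[][].*$", "\\1", alt[is_bnd])
  variant_set(chrom = chrom, pos = pos, ref = ref, alt = alt,
              vclass = vclass, vaf = vaf,
              cna_end = ifelse(vclass == "CNA", end, NA_integer_),
              cna_dir = ifelse(is_dup, "amp",
                        ifelse(is_del, "del", NA_character_)),
              sv_mate = sv_mate)
}

# Cheap structural pre-scan so malformed lines are reported with their line
# number (readVcf's own errors do not carry one).
check_vcf_lines <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L || is.na(suppressWarnings(as.integer(f[2L]))))
      abort_evorisk(sprintf("malformed VCF line %d in '%s'", i, path),
                    "evorisk_parse_error")
  }
  invisible(TRUE)
}
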