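#' Read a reference genome from FASTA
#'
#' Loads a FASTA file into a named character vector of uppercase contig
#' sequences (the in-memory reference-genome representation used throughout
#' the package). Only `A/C/G/T/N` are permitted.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(seqs))
  names(g) <- sub("\\s.*$", "", names(seqs))
  validate_genome(g)
}

#' @rdname read_genome
#' @param genome Named character vector of contig sequences.
#' @export
validate_genome <- function(genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    abort_evorisk("contig names must be present and unique",
                  "evorisk_validation_error")
  if (any(grepl("[^ACGTN]", genome)))
    abort_evorisk("genome sequences may only contain A/C/G/T/N",
                  "evorisk_validation_error")
  genome
}

#' Write a genome to FASTA
#' @inheritParams validate_genome
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  validate_genome(genome)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome), filepath = path, width = width)
  invisible(path)
}

#' Fetch the trinucleotide context around a position
#'
#' Returns the 3-mer centered at `pos` on `chrom`, the left and right
#' neighbours plus the central base. Positions at a contig edge have no
#' full context: such variants are excluded from the 96 trinucleotide
#' features but still count toward the total SNV rate.
#'
#' @inheritParams validate_genome
#' @param chrom Contig name; unknown contigs are a hard error (silent
#'   skipping would deflate features).
#' @param pos 1-based position, `2 <= pos <= contig length - 1`.
#' @return 3-character string. Contexts containing `N` are returned as-is;
#'   downstream classification treats them as ambiguous.
#' @export
#' @examples
#' fetch_context(c(chrA = "ACGTA"), "chrA", 3) # "CGT"
fetch_context <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome))
    abort_evorisk(sprintf("contig '%s' not in reference", chrom),
                  "evorisk_contig_error")
  s <- genome[[chrom]]
  if (pos < 2L || pos > nchar(s) - 1L)
    abort_evorisk(sprintf("no full trinucleotide context at %s:%d", chrom, pos),
                  "evorisk_context_error")
  substr(s, pos - 1L, pos + 1L)
}

# Vectorized, error-free context lookup used by the feature extractor:
# returns NA where no full context exists instead of raising.
fetch_context_safe <- function(genome, chrom, pos) {
  lens <- nchar(genome)
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 2L & pos <= lens[chrom] - 1L
  if (any(ok))
    out[ok] <- substr(genome[chrom[ok]], pos[ok] - 1L, pos[ok] + 1L)
  out
}

#' Generate the toy reference genome
#'
#' A small random genome (default three 1-Mb contigs, fixed seed) standing
#' in for a human reference in simulations and tests. Generated in code so
#' no sequence data ships with the package.
#'
#' @param n_contigs Number of contigs.
#' @param contig_len Length of each contig in bp.
#' @param seed RNG seed; the default genome is a fixed, documented world.
#' @return Named character vector of contig sequences.
#' @export
toy_genome <- function(n_contigs = 3L, contig_len = 1e6, seed = 20210312L) {
  with_seed(seed, {
    g <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(BASES, contig_len, replace = TRUE), collapse = "")
    }, character(1L))
    names(g) <- paste0("chr", seq_len(n_contigs))
    g
  })
}
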