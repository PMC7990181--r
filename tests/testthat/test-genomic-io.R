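test_that("variant records enforce their invariants", {
  v <- variant_set(chrom = "chr1", pos = 100, ref = "C", alt = "A",
                   vclass = "SNV", vaf = 0.4)
  expect_s3_class(v, "evorisk_variants")
  expect_identical(v$pos, 100L)
  expect_error(variant_set("chr1", 100, "C", "C", "SNV", 0.4),
               class = "evorisk_validation_error")
  expect_error(variant_set("chr1", 100, "X", "A", "SNV", 0.4),
               class = "evorisk_validation_error")
  expect_error(variant_set("chr1", 100, "C", "A", "SNV", 1.4),
               class = "evorisk_validation_error")
  expect_error(variant_set("chr1", 0, "C", "A", "SNV", 0.4),
               class = "evorisk_validation_error")
  # CNA needs end >= pos and a direction
  expect_error(variant_set("chr1", 1000, "N", "<DEL>", "CNA", 0.2,
                           cna_end = 500, cna_dir = "del"),
               class = "evorisk_validation_error")
  expect_error(variant_set("chr1", 1000, "N", "<DEL>", "CNA", 0.2,
                           cna_end = 2000, cna_dir = NA),
               class = "evorisk_validation_error")
})

test_that("VCF write/read round-trips all variant classes at 1-based pos", {
  v <- variant_set(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr1"),
    pos = c(100L, 5000L, 100000L, 2500L, 77L),
    ref = c("C", "AT", "N", "G", "G"),
    alt = c("A", "A", "<DEL>", "G[chr1:900[", "<DUP>"),
    vclass = c("SNV", "INDEL", "CNA", "SV", "CNA"),
    vaf = c(0.4, 0.21, NA, 0.5, 0.12),
    cna_end = c(NA, NA, 700000L, NA, 150L),
    cna_dir = c(NA, NA, "del", NA, "amp"),
    sv_mate = c(NA, NA, NA, "chr1:900", NA))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, path, sample = "T1")
  back <- read_vcf(path, sample = "T1")
  expect_equal(as.data.frame(back), as.data.frame(v),
               ignore_attr = TRUE, tolerance = 1e-9)
  # symbolic CNA convention: <DEL> + END carries length end - pos + 1
  cna <- back[back$vclass == "CNA" & back$cna_dir == "del", ]
  expect_identical(cna$cna_end - cna$pos + 1L, 600001L)
})

test_that("malformed VCF lines are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tC\tA\t.\tPASS\t.",
               "chr1\tnot_a_pos\t.\tC\tA"), path)
  expect_error(read_vcf(path), "line 4", class = "evorisk_parse_error")
})

test_that("trinucleotide context fetch honors edges and unknown contigs", {
  g <- c(chrA = "ACGTA", chrB = "ACNTA")
  expect_identical(fetch_context(g, "chrA", 3), "CGT")
  expect_error(fetch_context(g, "chrA", 1), class = "evorisk_context_error")
  expect_error(fetch_context(g, "chrA", 5), class = "evorisk_context_error")
  expect_error(fetch_context(g, "chrZ", 3), class = "evorisk_contig_error")
  # ambiguous context propagates as NA class, not an error
  expect_identical(fetch_context(g, "chrB", 2), "ACN")
  expect_true(is.na(trinucleotide_class("CNT", "N", "A")))
})

test_that("FASTA write/read round-trips and validates the alphabet", {
  g <- toy_genome(n_contigs = 2, contig_len = 500, seed = 3)
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, path)
  expect_identical(read_genome(path), g)
  expect_error(validate_genome(c(chr1 = "ACGTQ")),
               class = "evorisk_validation_error")
  expect_error(validate_genome(c("ACGT", "ACGT")),
               class = "evorisk_validation_error")
})

test_that("clone trees round-trip and reject broken structure", {
  tr <- clone_tree(
    nodes = c("normal", "C1"), root = "normal",
    parent = c(C1 = "normal"),
    edge_counts = matrix(c(30, 0, 0, 0), 1,
                         dimnames = list("C1", c("snv", "indel", "cna", "sv"))),
    prevalence = c(normal = 0.4, C1 = 0.6))
  expect_identical(unname(tr$edge_counts["C1", "snv"]), 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_clone_tree(tr, path)
  back <- read_clone_tree(path)
  expect_equal(back$edge_counts, tr$edge_counts)
  expect_equal(back$prevalence, tr$prevalence)
  expect_identical(back$parent, tr$parent)

  expect_error(clone_tree(c("normal", "C1"), "normal", c(C1 = "C1"),
                          tr$edge_counts),
               class = "evorisk_structure_error")
  expect_error(clone_tree(c("normal", "C1", "C2"), "normal",
                          c(C1 = "C2", C2 = "C1"),
                          matrix(0, 2, 4,
                                 dimnames = list(c("C1", "C2"),
                                                 c("snv", "indel", "cna",
                                                   "sv")))),
               class = "evorisk_structure_error")
  bad <- tr
  bad$edge_counts["C1", "snv"] <- -1
  expect_error(validate_clone_tree(bad), class = "evorisk_validation_error")
  bad2 <- tr
  bad2$prevalence <- c(normal = 0.4, C1 = 0.9)
  expect_error(validate_clone_tree(bad2), class = "evorisk_validation_error")
})

test_that("outcome tables parse, validate and count-conserve", {
  path <- withr::local_tempfile(fileext = ".tsv")
  n <- 90L
  df <- data.frame(sample = sprintf("S%02d", 1:n),
                   os_time = stats::runif(n, 1, 100),
                   os_event = rep(c(0, 1), length.out = n))
  df$os_time[1] <- 24.5; df$os_event[1] <- 1
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_outcomes(path, "os")
  expect_equal(nrow(rec), n)
  expect_equal(rec$time[1], 24.5)
  expect_equal(rec$event[1], 1)
  expect_error(survival_records("S1", -3, 1),
               class = "evorisk_validation_error")
  expect_error(survival_records("S1", 10, 2),
               class = "evorisk_validation_error")
})

test_that("clinical tables keep kind declarations through a round trip", {
  tab <- clinical_table(
    data.frame(sample = c("A", "B", "C"),
               age = c(50, 60, 70),
               status = c("yes", "no", "yes"),
               stage = c("i", "ii", "iii"),
               stringsAsFactors = FALSE),
    kinds = c(age = "continuous", status = "binary", stage = "categorical"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(tab, path)
  back <- read_clinical(path)
  expect_identical(back$kinds, tab$kinds)
  expect_equal(back$data, tab$data)
  expect_error(clinical_table(tab$data, kinds = c(age = "fancy")),
               class = "evorisk_config_error")
})

test_that("the joined cohort is the sorted sample intersection", {
  expect_message(
    got <- joined_cohort(c("B", "A", "C"), c("A", "B"), c("C", "A", "B")),
    "dropping 1")
  expect_identical(got, c("A", "B"))
})
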