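# Shared fixtures, generated in code. Simulation worlds used by the tests
# are scaled down (small toy genome, moderate mutation rates) so the suite
# stays inside its runtime budget; the package defaults keep the full-size
# stated world.

test_genome <- toy_genome(n_contigs = 2L, contig_len = 5e4, seed = 7L)

# Cohort config for module-level tests: fast, predictive, no driver links.
test_sim_config <- function(n = 80L, beta = default_beta(), seed = 1L,
                            genome = test_genome, ...) {
  sim_config(n_samples = n, genome = genome,
             snv_rate = list(meanlog = log(3), sdlog = 0.6),
             indel_rate = list(meanlog = log(0.5), sdlog = 0.5),
             cna_rate = list(meanlog = log(0.5), sdlog = 0.5),
             sv_rate = list(meanlog = log(0.2), sdlog = 0.5),
             drivers = toy_driver_catalog(n_drivers = 5L, genome = genome,
                                          width = 4000L),
             driver_link = list(),
             beta = beta,
             baseline = list(family = "exponential", rate = 0.004),
             censoring = list(family = "uniform", min = 12, max = 120),
             seed = seed, ...)
}

# One cached mid-size cohort reused across test files.
shared_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- simulate_cohort(test_sim_config(n = 80L, seed = 42L))
    }
    value
  }
})

shared_features <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      value <<- cohort_features(shared_cohort(), trinucleotide = FALSE)
    }
    value
  }
})

# Quick synthetic survival data without the genomic layer, for the
# statistical-kernel tests.
toy_surv <- function(n, beta = c(0.8, 0.5), p = length(beta),
                     base_rate = 0.02, cens = c(10, 100), seed = 1L) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n,
              dimnames = list(paste0("s", seq_len(n)), paste0("f", 1:p)))
  eta <- as.vector(X %*% beta)
  tt <- stats::rexp(n, base_rate * exp(eta))
  cc <- stats::runif(n, cens[1], cens[2])
  list(X = X, eta = eta,
       outcomes = survival_records(rownames(X), pmin(tt, cc),
                                   as.numeric(tt <= cc)))
}

# Redraw outcomes for an existing cohort under a new true beta (reusing the
# realized covariates), used by the fraction-recovery tests.
redraw_outcomes <- function(cohort, beta, seed,
                            baseline = list(family = "exponential",
                                            rate = 0.004),
                            censoring = list(family = "uniform", min = 12,
                                             max = 120)) {
  covs <- cohort$truth$covariates
  eta <- numeric(nrow(covs))
  for (cv in names(beta)) {
    z <- covs[[cv]]
    if (stats::sd(z) > 0)
      eta <- eta + beta[[cv]] * (z - mean(z)) / stats::sd(z)
  }
  set.seed(seed)
  draw_survival(eta, baseline, censoring, sample = rownames(covs))$records
}

# Independent brute-force oracles ---------------------------------------

# Eq-6 concordance by naive double loop.
ci_bruteforce <- function(eta, outcomes) {
  y <- outcomes$time; d <- outcomes$event
  num <- 0; den <- 0
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (d[i] == 1 && y[j] > y[i]) {
      den <- den + 1
      if (eta[j] < eta[i]) num <- num + 1
    }
  }
  num / den
}

# Negative log partial likelihood at beta = 0: sum of log risk-set sizes.
nll0_oracle <- function(outcomes) {
  y <- outcomes$time; d <- outcomes$event
  sum(vapply(which(d == 1), function(i) log(sum(y >= y[i])), numeric(1)))
}

# Naive per-class tally of cumulative features for the decomposition oracle.
tally_oracle <- function(variants, genome, edge_years = 10) {
  counts <- stats::setNames(numeric(96L), trinucleotide_classes())
  snv <- variants[variants$vclass == "SNV", , drop = FALSE]
  for (k in seq_len(nrow(snv))) {
    ctx <- tryCatch(fetch_context(genome, snv$chrom[k], snv$pos[k]),
                    error = function(e) NA_character_)
    if (is.na(ctx) || grepl("N", ctx)) next
    cl <- trinucleotide_class(ctx, snv$ref[k], snv$alt[k])
    if (!is.na(cl)) counts[cl] <- counts[cl] + 1
  }
  counts / edge_years
}
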