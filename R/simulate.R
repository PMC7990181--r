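.evorisk_cache <- new.env(parent = emptyenv())

# Index of genome positions by pyrimidine-centered trinucleotide context,
# memoized per genome (the toy genome is scanned once per session).
context_index <- function(genome) {
  key <- paste(names(genome), nchar(genome),
               substr(genome, 1L, 40L), collapse = "|")
  hit <- .evorisk_cache[[key]]
  if (!is.null(hit)) return(hit)
  rows <- lapply(names(genome), function(ch) {
    s <- genome[[ch]]
    n <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    center <- chars[2:(n - 1L)]
    pyr <- center %in% PYRIMIDINES
    pos <- which(pyr) + 1L
    ctx <- paste0(chars[pos - 1L], chars[pos], chars[pos + 1L])
    ok <- !grepl("N", ctx, fixed = TRUE)
    data.frame(chrom = ch, pos = pos[ok], ctx = ctx[ok],
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  idx <- split(all[c("chrom", "pos")], all$ctx)
  .evorisk_cache[[key]] <- idx
  idx
}

#' Default cohort signature mixture
#'
#' A smooth mixture over the 96 trinucleotide classes emulating an
#' aging-dominated mutational phenotype: `C>T` classes (especially in NpCpG
#' context) are enriched over a uniform background.
#'
#' @return Named numeric vector over the 96 classes summing to 1.
#' @export
default_signature_weights <- function() {
  cls <- trinucleotide_classes()
  w <- rep(1, length(cls))
  w[grepl("C>T", cls, fixed = TRUE)] <- 3
  w[grepl("\\[C>T\\]G", cls)] <- 6
  stats::setNames(w / sum(w), cls)
}

#' Default clinical covariate specification
#'
#' Age (continuous), neoplasm status (binary; the strong clinical
#' predictor) and tumor stage (3-level categorical).
#'
#' @return Named list of attribute specifications.
#' @export
default_clinical_spec <- function() {
  list(age = list(kind = "continuous", mean = 60, sd = 10),
       status = list(kind = "binary", levels = c("tumor-free", "with-tumor"),
                     p = 0.3),
       stage = list(kind = "categorical", levels = c("i", "ii", "iii"),
                    probs = c(0.5, 0.3, 0.2)))
}

#' Default true hazard coefficients
#'
#' Log-hazard coefficients on the standardized generative covariates,
#' mirroring the qualitative structure of real tumor cohorts: clinical
#' covariates (neoplasm status above all) carry the strongest hazard,
#' mutational-phenotype parameters a moderate one, a driver a small one.
#'
#' @return Named numeric vector.
#' @export
default_beta <- function() {
  c(log_snv_rate = 0.4, cna_rate = 0.3, drv_DRV01 = 0.2,
    age = 0.3, status = 0.9)
}

#' Hazard coefficients mixing evolutionary and clinical effects
#'
#' Convenience constructor for ground-truth-recovery experiments: the
#' evolutionary block (`log_snv_rate`, `cna_rate`) is scaled by `share`
#' and the clinical block (`age`, `status`) by `1 - share`, at an overall
#' strong effect size, so the generative share of evolutionary hazard is
#' the single knob.
#'
#' @param share Evolutionary share in `[0, 1]`.
#' @param scale Overall effect scale (log-hazard per covariate SD).
#' @return Named numeric vector usable as `beta` in [sim_config()].
#' @export
beta_mixture <- function(share, scale = 1.5) {
  stopifnot(share >= 0, share <= 1)
  c(log_snv_rate = 0.8 * share, cna_rate = 0.6 * share,
    age = 0.4 * (1 - share), status = 0.9 * (1 - share)) * scale
}

#' Simulation configuration
#'
#' The stated world for the synthetic cohorts: per-sample mutation-rate
#' parameters drawn from lognormal priors, SNVs placed by a
#' Dirichlet-dispersed trinucleotide signature mixture, CNAs with
#' direction and size classes straddling the 500,000-nt threshold, driver
#' hits optionally coupled to phenotype rates through multiplicative
#' links, independent clinical covariates, and censored survival times
#' from a proportional-hazards model with known coefficients. Default
#' event fractions mirror a breast-cancer-like cohort (roughly 15%
#' observed events for OS).
#'
#' @param n_samples Cohort size, `>= 2`.
#' @param genome Reference genome (named character vector).
#' @param signature_weights Mixture over the 96 trinucleotide classes
#'   (must sum to 1).
#' @param signature_dispersion Dirichlet concentration scale for
#'   per-sample mixture jitter.
#' @param snv_rate,indel_rate,cna_rate,sv_rate Lognormal priors
#'   (`meanlog`, `sdlog`) for the per-year event-rate parameters.
#' @param cna_amp_prob Probability a CNA is an amplification.
#' @param cna_len Lognormal length distribution of CNAs (nt).
#' @param drivers A `driver_catalog` of potential driver intervals.
#' @param driver_mut_prob Per-driver mutation probability.
#' @param driver_link Named list: driver name -> named multipliers applied
#'   to that sample's rate parameters when the driver is mutated (the
#'   driver-phenotype coupling).
#' @param clinical Clinical attribute specification
#'   (see [default_clinical_spec()]).
#' @param beta Named true log-hazard coefficients over generative
#'   covariates (standardized within the cohort before use).
#' @param baseline,dfs_baseline Baseline hazard family and parameters for
#'   the OS and DFS endpoints (`exponential` rate per month, or `weibull`
#'   with `shape` and `scale`).
#' @param censoring Censoring-time distribution (`uniform` min/max months,
#'   `exponential` rate, or `none`); independent of covariates.
#' @param edge_years Assumed normal-to-tumor edge duration.
#' @param clone_count Integer vector of admissible clone counts (sampled
#'   uniformly).
#' @param branched_prob Probability a multi-clone tree is branched rather
#'   than linear.
#' @param missing_context `"resample"` (reassign mass to placeable
#'   classes) or `"error"` when a drawn class has no matching context.
#' @param seed Master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200L,
                       genome = toy_genome(),
                       signature_weights = default_signature_weights(),
                       signature_dispersion = 50,
                       snv_rate = list(meanlog = log(10), sdlog = 0.6),
                       indel_rate = list(meanlog = log(1), sdlog = 0.5),
                       cna_rate = list(meanlog = log(0.8), sdlog = 0.5),
                       sv_rate = list(meanlog = log(0.4), sdlog = 0.5),
                       cna_amp_prob = 0.5,
                       cna_len = list(meanlog = log(3e5), sdlog = 1),
                       drivers = toy_driver_catalog(genome = genome),
                       driver_mut_prob = 0.1,
                       driver_link = list(DRV01 = c(cna_rate = 2),
                                          DRV02 = c(snv_rate = 1.5)),
                       clinical = default_clinical_spec(),
                       beta = default_beta(),
                       baseline = list(family = "exponential", rate = 0.002),
                       dfs_baseline = list(family = "exponential",
                                           rate = 0.003),
                       censoring = list(family = "uniform", min = 12,
                                        max = 120),
                       edge_years = 10,
                       clone_count = 1:5,
                       branched_prob = 0.5,
                       missing_context = c("resample", "error"),
                       seed = 1L) {
  if (n_samples < 2L)
    abort_evorisk("n_samples must be >= 2", "evorisk_config_error")
  if (abs(sum(signature_weights) - 1) > 1e-8 || any(signature_weights < 0))
    abort_evorisk("signature weights must be a distribution over 96 classes",
                  "evorisk_config_error")
  if (!setequal(names(signature_weights), trinucleotide_classes()))
    abort_evorisk("signature weights must be named by the 96 classes",
                  "evorisk_config_error")
  if (any(nchar(genome) < 3L) ||
      (sum(nchar(genome)) == 0 && exp(snv_rate$meanlog) > 0))
    abort_evorisk("degenerate genome for requested mutation rates",
                  "evorisk_config_error")
  structure(list(n_samples = as.integer(n_samples), genome = genome,
                 signature_weights = signature_weights,
                 signature_dispersion = signature_dispersion,
                 snv_rate = snv_rate, indel_rate = indel_rate,
                 cna_rate = cna_rate, sv_rate = sv_rate,
                 cna_amp_prob = cna_amp_prob, cna_len = cna_len,
                 drivers = drivers, driver_mut_prob = driver_mut_prob,
                 driver_link = driver_link, clinical = clinical,
                 beta = beta, baseline = baseline,
                 dfs_baseline = dfs_baseline, censoring = censoring,
                 edge_years = edge_years, clone_count = clone_count,
                 branched_prob = branched_prob,
                 missing_context = match.arg(missing_context),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw signature-placed SNVs for one sample
#'
#' Draws per-class counts from a multinomial over the 96 trinucleotide
#' classes and places each SNV at a genome position whose (pyrimidine-
#' centered) context matches its class, emitting the matching ref/alt
#' bases and a random VAF.
#'
#' @param n_snv Number of SNVs.
#' @param weights Mixture over the 96 classes.
#' @param genome Reference genome.
#' @param missing_context See [sim_config()].
#' @return An `evorisk_variants` set of SNV records.
#' @export
draw_snvs <- function(n_snv, weights, genome,
                      missing_context = "resample") {
  cls <- trinucleotide_classes()
  weights <- weights[cls]
  idx <- context_index(genome)
  ctx_of <- paste0(substr(cls, 1L, 1L), substr(cls, 3L, 3L),
                   substr(cls, 7L, 7L))
  placeable <- ctx_of %in% names(idx)
  if (any(!placeable & weights > 0)) {
    if (missing_context == "error")
      abort_evorisk("signature class with no matching context in genome",
                    "evorisk_config_error")
    weights[!placeable] <- 0
    if (sum(weights) == 0)
      abort_evorisk("no placeable signature class", "evorisk_config_error")
    weights <- weights / sum(weights)
  }
  if (n_snv == 0L) return(variant_set())
  counts <- as.vector(stats::rmultinom(1L, n_snv, weights))
  hot <- which(counts > 0L)
  chroms <- vector("list", length(hot)); poss <- chroms
  for (h in seq_along(hot)) {
    k <- hot[h]
    sites <- idx[[ctx_of[k]]]
    take <- sample.int(nrow(sites), counts[k],
                       replace = counts[k] > nrow(sites))
    chroms[[h]] <- sites$chrom[take]
    poss[[h]] <- sites$pos[take]
  }
  variant_set(chrom = unlist(chroms, use.names = FALSE),
              pos = unlist(poss, use.names = FALSE),
              ref = rep(substr(cls[hot], 3L, 3L), counts[hot]),
              alt = rep(substr(cls[hot], 5L, 5L), counts[hot]),
              vclass = "SNV", vaf = stats::runif(n_snv, 0.05, 0.6))
}

#' Draw censored survival times under proportional hazards
#'
#' Inverse-transform sampling from `h(t) exp(eta)`: with an exponential
#' baseline of rate `r`, event times are `Exp(r exp(eta))`; with a
#' Weibull baseline, `scale * (E / exp(eta))^(1/shape)` for `E ~ Exp(1)`.
#' Censoring times are drawn independently of covariates; the follow-up
#' is `y = min(T, C)` with event indicator `1[T <= C]`.
#'
#' @param eta True per-sample linear predictors (log relative hazard).
#' @param baseline Baseline hazard: `list(family = "exponential", rate)`
#'   or `list(family = "weibull", shape, scale)`.
#' @param censoring `list(family = "uniform", min, max)`,
#'   `list(family = "exponential", rate)`, or `list(family = "none")`.
#' @param sample Sample ids.
#' @return List with `records` (a `survival_records`) and `event_time`
#'   (uncensored times, the ground truth).
#' @export
draw_survival <- function(eta, baseline = list(family = "exponential",
                                               rate = 0.002),
                          censoring = list(family = "none"),
                          sample = paste0("S", seq_along(eta))) {
  n <- length(eta)
  T_true <- switch(baseline$family,
    exponential = {
      if (baseline$rate <= 0)
        abort_evorisk("baseline rate must be positive",
                      "evorisk_config_error")
      stats::rexp(n, rate = baseline$rate * exp(eta))
    },
    weibull = {
      if (baseline$shape <= 0 || baseline$scale <= 0)
        abort_evorisk("Weibull parameters must be positive",
                      "evorisk_config_error")
      baseline$scale * (stats::rexp(n, 1) / exp(eta))^(1 / baseline$shape)
    },
    abort_evorisk("baseline family must be exponential or weibull",
                  "evorisk_config_error"))
  C <- switch(censoring$family,
    none = rep(Inf, n),
    uniform = stats::runif(n, censoring$min, censoring$max),
    exponential = stats::rexp(n, censoring$rate),
    abort_evorisk("unknown censoring family", "evorisk_config_error"))
  y <- pmin(T_true, C)
  y <- pmax(y, .Machine$double.eps)
  list(records = survival_records(sample, y, as.numeric(T_true <= C)),
       event_time = T_true)
}

#' Partition realized variants onto a random clone tree
#'
#' Samples a clone count and topology (linear chain or random branched
#' tree), distributes the sample's variants uniformly over the edges, and
#' draws tree-consistent prevalences (clone fractions from a Dirichlet,
#' assigned in depth order so a child's prevalence never exceeds its
#' parent's; fractions sum to at most 1 with the normal compartment).
#'
#' @param variants The sample's `evorisk_variants`.
#' @param n_clones Clone count; drawn uniformly from `clone_count` when
#'   `NULL`. Requesting more clones than variants is an error.
#' @param branched Force branched (`TRUE`) / linear (`FALSE`) topology;
#'   drawn with probability `branched_prob` when `NULL`.
#' @param clone_count,branched_prob Defaults for the random draws.
#' @return A `clone_tree` whose per-edge class counts sum to the realized
#'   variant counts by class.
#' @export
build_clone_tree <- function(variants, n_clones = NULL, branched = NULL,
                             clone_count = 1:5, branched_prob = 0.5) {
  n_var <- nrow(variants)
  if (is.null(n_clones)) {
    cand <- clone_count[clone_count <= max(n_var, 1L)]
    if (!length(cand)) cand <- 1L
    n_clones <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  if (n_clones > 1L && n_clones > n_var)
    abort_evorisk("more clones than variants to distribute",
                  "evorisk_config_error")
  if (is.null(branched)) branched <- stats::runif(1) < branched_prob
  clones <- paste0("C", seq_len(n_clones))
  nodes <- c("normal", clones)
  parent <- character(0)
  if (n_clones >= 1L) {
    parent <- stats::setNames(character(n_clones), clones)
    parent[1L] <- "normal"
    if (n_clones > 1L) {
      for (j in 2:n_clones) {
        parent[j] <- if (branched) {
          sample(c("normal", clones[seq_len(j - 1L)]), 1L)
        } else clones[j - 1L]
      }
    }
  }
  ec <- matrix(0, nrow = n_clones, ncol = length(MUT_CLASSES),
               dimnames = list(clones, MUT_CLASSES))
  if (n_var > 0L) {
    edge_of <- sample.int(n_clones, n_var, replace = TRUE)
    cls_low <- tolower(variants$vclass)
    cls_low[cls_low == "indel"] <- "indel"
    for (k in seq_len(n_var))
      ec[edge_of[k], cls_low[k]] <- ec[edge_of[k], cls_low[k]] + 1
  }
  # depth-ordered Dirichlet fractions: shallower clones get larger mass
  fr <- stats::rgamma(n_clones + 1L, shape = 1)
  fr <- fr / sum(fr)
  clone_fr <- sort(fr[-1L], decreasing = TRUE)
  tr0 <- structure(list(nodes = nodes, root = "normal", parent = parent,
                        edge_counts = ec, prevalence = NULL),
                   class = "clone_tree")
  depth <- vapply(clones, function(nd) length(path_to_root(tr0, nd)),
                  numeric(1L))
  prev <- stats::setNames(numeric(n_clones), clones[order(depth)])
  prev[] <- clone_fr
  prev <- c(normal = unname(fr[1L]), prev)
  clone_tree(nodes = nodes, root = "normal", parent = parent,
             edge_counts = ec, prevalence = prev[nodes])
}

draw_clinical_value <- function(spec, n) {
  switch(spec$kind,
    continuous = stats::rnorm(n, spec$mean, spec$sd),
    binary = spec$levels[1L + stats::rbinom(n, 1L, spec$p)],
    categorical = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    abort_evorisk("unknown clinical kind", "evorisk_config_error"))
}

clinical_covariate <- function(spec, values) {
  switch(spec$kind,
    continuous = as.numeric(values),
    binary = as.numeric(values == spec$levels[2L]),
    categorical = as.numeric(match(values, spec$levels)))
}

#' Simulate a full synthetic cohort
#'
#' Realizes the world described by a [sim_config()]: per-sample phenotype
#' parameters, VCF-writable variant lists, clone trees whose edge counts
#' conserve the realized variant counts, clinical covariates, censored OS
#' and DFS outcomes generated under proportional hazards with the
#' configured true coefficients, and the full ground truth needed by
#' recovery tests. Identical configuration (including seed) gives
#' identical output.
#'
#' @param config A `sim_config`.
#' @return List of class `sim_cohort`: `variants` (named list), `trees`
#'   (named list), `clinical` (`clinical_table`), `outcomes` (list with
#'   `os` and `dfs` `survival_records`), `truth` (phenotype parameter
#'   table, standardized design, `beta`, `eta`, uncensored event times),
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    genome <- config$genome
    contigs <- names(genome)
    clens <- nchar(genome)
    rate_names <- c("snv_rate", "indel_rate", "cna_rate", "sv_rate")
    rates <- vapply(rate_names, function(rn) {
      pr <- config[[rn]]
      stats::rlnorm(n, pr$meanlog, pr$sdlog)
    }, numeric(n))
    rownames(rates) <- ids
    drv_names <- unique(config$drivers$name)
    drv_hit <- matrix(stats::rbinom(n * length(drv_names), 1L,
                                    config$driver_mut_prob),
                      nrow = n, dimnames = list(ids, drv_names))
    for (dn in names(config$driver_link)) {
      if (!dn %in% drv_names) next
      mult <- config$driver_link[[dn]]
      for (rn in names(mult))
        rates[, rn] <- rates[, rn] * ifelse(drv_hit[, dn] == 1L, mult[[rn]], 1)
    }
    variants <- vector("list", n); names(variants) <- ids
    trees <- vector("list", n); names(trees) <- ids
    for (i in seq_len(n)) {
      ey <- config$edge_years
      w_i <- stats::rgamma(96L, shape = config$signature_dispersion *
                             config$signature_weights)
      if (sum(w_i) == 0) w_i <- config$signature_weights else
        w_i <- w_i / sum(w_i)
      names(w_i) <- names(config$signature_weights)
      n_snv <- stats::rpois(1L, rates[i, "snv_rate"] * ey)
      snvs <- draw_snvs(n_snv, w_i, genome, config$missing_context)
      # driver point mutations: one literal SNV inside each hit driver
      hit <- drv_names[drv_hit[i, ] == 1L]
      if (length(hit)) {
        iv <- config$drivers[match(hit, config$drivers$name), , drop = FALSE]
        dpos <- iv$start + vapply(iv$end - iv$start, function(wd)
          sample.int(wd + 1L, 1L) - 1L, integer(1L))
        dref <- substr(genome[iv$chrom], dpos, dpos)
        dalt <- vapply(dref, function(b) sample(setdiff(BASES, b), 1L),
                       character(1L), USE.NAMES = FALSE)
        ok <- dref %in% BASES
        if (any(ok))
          snvs <- rbind(snvs, variant_set(
            chrom = iv$chrom[ok], pos = dpos[ok], ref = dref[ok],
            alt = dalt[ok], vclass = "SNV",
            vaf = stats::runif(sum(ok), 0.05, 0.6)))
      }
      n_indel <- stats::rpois(1L, rates[i, "indel_rate"] * ey)
      indels <- NULL
      if (n_indel > 0L) {
        ch <- sample(contigs, n_indel, replace = TRUE,
                     prob = clens / sum(clens))
        pos <- 1L + as.integer(ceiling(stats::runif(n_indel) *
                                         (clens[ch] - 2L)))
        ref2 <- substr(genome[ch], pos, pos + 1L)
        indels <- variant_set(chrom = ch, pos = pos, ref = ref2,
                              alt = substr(ref2, 1L, 1L), vclass = "INDEL",
                              vaf = stats::runif(n_indel, 0.05, 0.6))
      }
      n_cna <- stats::rpois(1L, rates[i, "cna_rate"] * ey)
      cnas <- NULL
      if (n_cna > 0L) {
        ch <- sample(contigs, n_cna, replace = TRUE,
                     prob = clens / sum(clens))
        start <- as.integer(ceiling(stats::runif(n_cna) * (clens[ch] - 1L)))
        len <- pmax(2L, as.integer(stats::rlnorm(n_cna, config$cna_len$meanlog,
                                                 config$cna_len$sdlog)))
        end <- pmin(start + len - 1L, clens[ch])
        dirs <- ifelse(stats::runif(n_cna) < config$cna_amp_prob,
                       "amp", "del")
        cnas <- variant_set(chrom = ch, pos = start, ref = "N",
                            alt = ifelse(dirs == "amp", "<DUP>", "<DEL>"),
                            vclass = "CNA",
                            vaf = stats::runif(n_cna, 0.05, 0.6),
                            cna_end = end, cna_dir = dirs)
      }
      n_sv <- stats::rpois(1L, rates[i, "sv_rate"] * ey)
      svs <- NULL
      if (n_sv > 0L) {
        ch <- sample(contigs, n_sv, replace = TRUE, prob = clens / sum(clens))
        pos <- as.integer(ceiling(stats::runif(n_sv) * clens[ch]))
        mch <- sample(contigs, n_sv, replace = TRUE)
        mpos <- as.integer(ceiling(stats::runif(n_sv) * clens[mch]))
        sref <- substr(genome[ch], pos, pos)
        svs <- variant_set(chrom = ch, pos = pos,
                           ref = sref,
                           alt = sprintf("%s[%s:%d[", sref, mch, mpos),
                           vclass = "SV",
                           vaf = stats::runif(n_sv, 0.05, 0.6),
                           sv_mate = paste0(mch, ":", mpos))
      }
      v <- rbind(snvs, indels, cnas, svs)
      class(v) <- c("evorisk_variants", "data.frame")
      variants[[i]] <- v
      trees[[i]] <- build_clone_tree(v, clone_count = config$clone_count,
                                     branched_prob = config$branched_prob)
    }
    clin_vals <- lapply(config$clinical, draw_clinical_value, n = n)
    clin_df <- data.frame(sample = ids, stringsAsFactors = FALSE)
    for (a in names(clin_vals)) clin_df[[a]] <- clin_vals[[a]]
    clinical <- clinical_table(clin_df, kinds = stats::setNames(
      vapply(config$clinical, `[[`, "", "kind"), names(config$clinical)))

    covs <- data.frame(log_snv_rate = log(rates[, "snv_rate"]),
                       log_indel_rate = log(rates[, "indel_rate"]),
                       cna_rate = rates[, "cna_rate"],
                       sv_rate = rates[, "sv_rate"], row.names = ids)
    for (dn in drv_names) covs[[paste0("drv_", dn)]] <- drv_hit[, dn]
    for (a in names(config$clinical))
      covs[[a]] <- clinical_covariate(config$clinical[[a]], clin_vals[[a]])

    eta <- numeric(n)
    used <- intersect(names(config$beta), names(covs))
    if (length(setdiff(names(config$beta), names(covs))))
      abort_evorisk("beta names outside generative covariates",
                    "evorisk_config_error")
    for (cv in used) {
      z <- covs[[cv]]
      sdz <- stats::sd(z)
      if (sdz > 0) eta <- eta + config$beta[[cv]] * (z - mean(z)) / sdz
    }
    os <- draw_survival(eta, config$baseline, config$censoring, sample = ids)
    dfs <- draw_survival(eta, config$dfs_baseline, config$censoring,
                         sample = ids)
    structure(list(variants = variants, trees = trees, clinical = clinical,
                   outcomes = list(os = os$records, dfs = dfs$records),
                   truth = list(rates = as.data.frame(rates),
                                driver_hits = drv_hit,
                                covariates = covs, beta = config$beta,
                                eta = stats::setNames(eta, ids),
                                event_time = list(os = os$event_time,
                                                  dfs = dfs$event_time)),
                   config = config),
              class = "sim_cohort")
  })
}

#' Write a simulated cohort to disk
#'
#' Materializes a cohort as the on-disk formats the extraction pipeline
#' reads: one VCF and one clone-tree JSON per sample, the reference FASTA,
#' `clinical.tsv`, `outcomes.tsv` and `ground_truth.json`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  write_genome(cohort$config$genome, file.path(dir, "genome.fa"))
  for (id in names(cohort$variants)) {
    write_vcf(cohort$variants[[id]], file.path(dir, "vcf",
                                               paste0(id, ".vcf")),
              sample = id)
    write_clone_tree(cohort$trees[[id]],
                     file.path(dir, "trees", paste0(id, ".json")))
  }
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_outcomes(cohort$outcomes, file.path(dir, "outcomes.tsv"))
  jsonlite::write_json(
    list(beta = as.list(cohort$truth$beta),
         eta = as.list(cohort$truth$eta),
         rates = cohort$truth$rates),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Feature matrix and outcomes of a simulated cohort
#'
#' Convenience wrapper running the full extraction on an in-memory
#' cohort: evolutionary features (cumulative + phylogenetic), driver
#' features against the configured catalog, encoded clinical covariates,
#' assembled and aligned with the requested endpoint.
#'
#' @param cohort A `sim_cohort`.
#' @param endpoint `"os"` or `"dfs"`.
#' @param trinucleotide Include the 96 trinucleotide rate features?
#' @return List with `features` ([feature_matrix()]) and `outcomes`.
#' @export
cohort_features <- function(cohort, endpoint = "os", trinucleotide = TRUE) {
  evo <- evolutionary_features(cohort$variants, cohort$config$genome,
                               trees = cohort$trees,
                               edge_years = cohort$config$edge_years,
                               trinucleotide = trinucleotide)
  drv <- driver_features(cohort$variants, cohort$config$drivers,
                         edge_years = cohort$config$edge_years)
  cli <- encode_clinical(cohort$clinical, quiet = TRUE)
  assemble_matrix(evo, drv, cli, outcomes = cohort$outcomes[[endpoint]],
                  quiet = TRUE)
}
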