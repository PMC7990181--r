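#' Configuration for the selection pipeline
#'
#' Bundles every tunable of the model-selection machinery: the collinearity
#' threshold, the step-wise selection cap, the two-loop cross-validation
#' layout (3-fold outer, repeated five times, with a 3-fold or leave-one-out
#' inner loop), the bootstrap protocol (1,000 trials drawing 80% of the
#' candidate features and 80% of the samples with replacement), and the
#' lasso penalty grid.
#'
#' @param corr_threshold Absolute Pearson correlation above which one of a
#'   feature pair is dropped.
#' @param max_k Cap on the number of step-wise selected features.
#' @param outer_folds,outer_repeats Outer CV layout.
#' @param inner_scheme `"kfold"` or `"loocv"` (the latter mirrors
#'   small-cohort handling).
#' @param inner_folds Folds of the inner k-fold scheme.
#' @param n_boot,boot_feature_frac,boot_sample_frac Bootstrap protocol.
#' @param lambda_grid l1 penalty grid for the lasso variant.
#' @param seed Master seed; pruning randomness, fold shuffling and
#'   bootstrap draws each consume their own stream derived from it.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(corr_threshold = 0.8, max_k = 10L,
                             outer_folds = 3L, outer_repeats = 5L,
                             inner_scheme = c("kfold", "loocv"),
                             inner_folds = 3L, n_boot = 1000L,
                             boot_feature_frac = 0.8, boot_sample_frac = 0.8,
                             lambda_grid = c(0.03, 0.1, 0.3, 1, 3, 10, 30),
                             seed = 1L) {
  inner_scheme <- match.arg(inner_scheme)
  stopifnot(boot_feature_frac > 0, boot_feature_frac <= 1,
            boot_sample_frac > 0, boot_sample_frac <= 1,
            outer_folds >= 2L, inner_folds >= 2L, max_k >= 1L,
            corr_threshold > 0)
  structure(list(corr_threshold = corr_threshold, max_k = as.integer(max_k),
                 outer_folds = as.integer(outer_folds),
                 outer_repeats = as.integer(outer_repeats),
                 inner_scheme = inner_scheme,
                 inner_folds = as.integer(inner_folds),
                 n_boot = as.integer(n_boot),
                 boot_feature_frac = boot_feature_frac,
                 boot_sample_frac = boot_sample_frac,
                 lambda_grid = lambda_grid, seed = as.integer(seed)),
            class = "selection_config")
}

#' Subset a feature matrix by class tag
#' @param features A [feature_matrix()].
#' @param classes Character vector of tags to keep.
#' @return A `feature_matrix` restricted to the tagged columns.
#' @export
subset_classes <- function(features, classes) {
  keep <- names(features$classes)[features$classes %in% classes]
  if (!length(keep))
    abort_evorisk("no features carry the requested class tags",
                  "evorisk_validation_error")
  feature_matrix(features$x[, keep, drop = FALSE], features$classes[keep])
}

#' Drop one member of each highly correlated feature pair
#'
#' Greedy pass over all feature pairs in column order: whenever two
#' retained features have absolute Pearson correlation above the threshold,
#' one of the two is dropped by a seeded coin flip. Zero-variance columns
#' (undefined correlation) are dropped first.
#'
#' @param x Numeric matrix (samples x features).
#' @param threshold Absolute correlation threshold (default 0.8).
#' @param seed Seed for the coin flips.
#' @return List with `x` (reduced matrix), `dropped` (character vector) and
#'   `pairs` (data frame logging each flagged pair and the survivor).
#' @export
prune_collinear <- function(x, threshold = 0.8, seed = 1L) {
  zero_var <- apply(x, 2L, stats::sd) == 0
  dropped <- colnames(x)[zero_var]
  x <- x[, !zero_var, drop = FALSE]
  log_rows <- list()
  if (ncol(x) >= 2L) {
    cc <- suppressWarnings(stats::cor(x))
    keep <- rep(TRUE, ncol(x))
    with_seed(seed, {
      for (i in seq_len(ncol(x) - 1L)) {
        if (!keep[i]) next
        for (j in seq((i + 1L), ncol(x))) {
          if (!keep[j] || is.na(cc[i, j])) next
          if (abs(cc[i, j]) > threshold) {
            drop_first <- stats::runif(1) < 0.5
            victim <- if (drop_first) i else j
            keep[victim] <- FALSE
            log_rows[[length(log_rows) + 1L]] <- data.frame(
              kept = colnames(x)[if (drop_first) j else i],
              dropped = colnames(x)[victim], r = cc[i, j],
              stringsAsFactors = FALSE)
            if (drop_first) break
          }
        }
      }
    })
    dropped <- c(dropped, colnames(x)[!keep])
    x <- x[, keep, drop = FALSE]
  }
  list(x = x,
       dropped = dropped,
       pairs = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(kept = character(), dropped = character(),
                    r = numeric()))
}

# Inner-CV concordance of one candidate feature set: fit per inner training
# split, pool all held-out risk scores, compute a single CI (a per-fold CI
# is undefined for leave-one-out). Returns NA on universal fit failure.
inner_cv_score <- function(x, outcomes, cols, fold_id, lambda = 0) {
  eta <- rep(NA_real_, nrow(x))
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    fit <- tryCatch(
      cox_fit(x[tr, cols, drop = FALSE], outcomes[tr, , drop = FALSE],
              lambda = lambda),
      evorisk_error = function(e) NULL, error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$coef))) return(NA_real_)
    eta[!tr] <- as.vector(-x[!tr, cols, drop = FALSE] %*% fit$coef)
  }
  tryCatch(concordance_index(eta, outcomes),
           evorisk_error = function(e) NA_real_)
}

inner_fold_ids <- function(n, events, scheme, k, seed) {
  if (scheme == "loocv") return(seq_len(n))
  for (try in seq_len(100L)) {
    ids <- with_seed(child_seed(seed, paste0("innerfold", try)),
                     sample(rep_len(seq_len(k), n)))
    ok <- all(vapply(seq_len(k), function(f) sum(events[ids != f]) >= 1,
                     logical(1L)))
    if (ok) return(ids)
  }
  seq_len(n) %% k + 1L
}

#' Step-wise forward l0 feature selection
#'
#' The heuristic for the l0-constrained Cox objective: starting from the
#' empty set, every unselected feature is evaluated joined to the current
#' set by inner-CV concordance of a Cox fit, the best one is added, and
#' selection stops as soon as the inner-CV concordance no longer strictly
#' increases (or `max_k` is reached). Ties between candidates break to the
#' lowest column index so runs are deterministic.
#'
#' @param x Numeric training matrix (already pruned).
#' @param outcomes Aligned `survival_records`.
#' @param inner_scheme `"kfold"` or `"loocv"`.
#' @param inner_folds Number of inner folds for `"kfold"`.
#' @param max_k Selection cap.
#' @param seed Seed for the inner fold assignment.
#' @return List with `selected` (character vector, selection order) and
#'   `trace` (inner-CV CI after each accepted step, nondecreasing).
#' @export
stepwise_l0 <- function(x, outcomes, inner_scheme = "kfold",
                        inner_folds = 3L, max_k = 10L, seed = 1L) {
  p <- ncol(x)
  fold_id <- inner_fold_ids(nrow(x), outcomes$event, inner_scheme,
                            inner_folds, seed)
  selected <- integer()
  best_ci <- -Inf
  trace <- numeric()
  while (length(selected) < min(max_k, p)) {
    cands <- setdiff(seq_len(p), selected)
    scores <- vapply(cands, function(cidx) {
      inner_cv_score(x, outcomes, c(selected, cidx), fold_id)
    }, numeric(1L))
    if (all(is.na(scores))) {
      if (!length(selected))
        abort_evorisk("every single-feature fit failed: empty selection",
                      "evorisk_selection_error")
      break
    }
    best <- cands[which.max(scores)]   # which.max: first max, lowest index
    if (max(scores, na.rm = TRUE) > best_ci) {
      best_ci <- max(scores, na.rm = TRUE)
      selected <- c(selected, best)
      trace <- c(trace, best_ci)
    } else break
  }
  list(selected = colnames(x)[selected], trace = trace)
}

# Shared per-fold training pipeline: z-score with training statistics,
# prune, select, final fit; returns scores for the test rows. Test rows
# are transformed with the training statistics only.
fit_fold <- function(x_tr, x_te, out_tr, config, model, seed) {
  mu <- colMeans(x_tr)
  sg <- apply(x_tr, 2L, stats::sd)
  keep <- sg > 0
  if (!any(keep))
    abort_evorisk("no non-constant features in training fold",
                  "evorisk_selection_error")
  zs_tr <- scale(x_tr[, keep, drop = FALSE], mu[keep], sg[keep])
  zs_te <- scale(x_te[, keep, drop = FALSE], mu[keep], sg[keep])
  pr <- prune_collinear(zs_tr, config$corr_threshold,
                        seed = child_seed(seed, "prune"))
  if (model == "l0") {
    sel <- stepwise_l0(pr$x, out_tr, inner_scheme = config$inner_scheme,
                       inner_folds = config$inner_folds,
                       max_k = config$max_k, seed = child_seed(seed, "inner"))
    fit <- cox_fit(pr$x[, sel$selected, drop = FALSE], out_tr)
    used <- sel$selected
  } else {
    fold_id <- inner_fold_ids(nrow(pr$x), out_tr$event, config$inner_scheme,
                              config$inner_folds, child_seed(seed, "inner"))
    scores <- vapply(config$lambda_grid, function(lm) {
      inner_cv_score(pr$x, out_tr, seq_len(ncol(pr$x)), fold_id, lambda = lm)
    }, numeric(1L))
    lam <- config$lambda_grid[which.max(scores)]
    fit <- cox_fit(pr$x, out_tr, lambda = lam)
    used <- names(fit$coef)[fit$coef != 0]
  }
  eta <- as.vector(-zs_te[, names(fit$coef), drop = FALSE] %*% fit$coef)
  list(eta = stats::setNames(eta, rownames(x_te)), selected = used,
       model = fit)
}

outer_fold_ids <- function(n, events, k, seed) {
  for (try in seq_len(100L)) {
    ids <- with_seed(child_seed(seed, paste0("outerfold", try)),
                     sample(rep_len(seq_len(k), n)))
    ok <- all(vapply(seq_len(k), function(f) {
      sum(events[ids != f]) >= 2 && sum(events[ids == f]) >= 1
    }, logical(1L)))
    if (ok) return(ids)
  }
  warning("could not find folds with events in every split; using last draw")
  ids
}

#' Two-loop (nested) cross-validation
#'
#' The evaluation protocol: samples are shuffled and split into outer
#' folds; on each outer training set the full pipeline runs (z-scoring
#' with training statistics, collinearity pruning, l0 step-wise or lasso
#' selection tuned by the inner CV) and the held-out fold is scored with
#' the resulting model. Held-out risk scores are pooled within a replicate
#' to one concordance index; the whole procedure is repeated
#' `outer_repeats` times with fresh shuffles to quantify split-to-split
#' variation. No statistic the model sees is ever derived from its outer
#' test fold.
#'
#' @param features A [feature_matrix()] (subset it with [subset_classes()]
#'   to run single-class experiments).
#' @param outcomes Aligned `survival_records`.
#' @param config A [selection_config()].
#' @param model `"l0"` (step-wise) or `"lasso"`.
#' @param canary Optional name of a feature column whose *training-fold*
#'   values are zeroed out before scaling and selection in every fold
#'   (its held-out values are left untouched). A leak-free pipeline drops
#'   the constant column and can never select it; any implementation that
#'   lets outer-test rows reach the training-time statistics would see the
#'   planted values and select them. Used by the leakage tests.
#' @return List of class `cv_result`: `predictions` (sample, replicate,
#'   fold, eta), `ci` (per replicate), `ci_mean`, `ci_sd`, `selected`
#'   (per replicate x fold), `config`, `model`.
#' @export
two_loop_cv <- function(features, outcomes, config = selection_config(),
                        model = c("l0", "lasso"), canary = NULL) {
  model <- match.arg(model)
  x <- as_design(features)
  stopifnot(nrow(x) == nrow(outcomes))
  n <- nrow(x)
  preds <- list(); cis <- numeric(config$outer_repeats); selected <- list()
  for (r in seq_len(config$outer_repeats)) {
    rseed <- child_seed(config$seed, paste0("rep", r))
    fold_of <- outer_fold_ids(n, outcomes$event, config$outer_folds, rseed)
    eta <- rep(NA_real_, n)
    for (f in seq_len(config$outer_folds)) {
      te <- fold_of == f
      x_tr <- x[!te, , drop = FALSE]
      if (!is.null(canary)) {
        stopifnot(canary %in% colnames(x))
        x_tr[, canary] <- 0
      }
      fold <- fit_fold(x_tr, x[te, , drop = FALSE],
                       outcomes[!te, , drop = FALSE], config, model,
                       seed = child_seed(rseed, paste0("fold", f)))
      eta[te] <- fold$eta
      selected[[sprintf("rep%d_fold%d", r, f)]] <- fold$selected
      preds[[length(preds) + 1L]] <- data.frame(
        sample = outcomes$sample[te], replicate = r, fold = f,
        eta = fold$eta, stringsAsFactors = FALSE)
    }
    cis[r] <- concordance_index(eta, outcomes)
  }
  structure(list(predictions = do.call(rbind, preds), ci = cis,
                 ci_mean = mean(cis), ci_sd = stats::sd(cis),
                 selected = selected, config = config, model = model),
            class = "cv_result")
}

#' Bootstrap feature importance
#'
#' Repeats the prune-and-select stage on bootstrap resamples -- by default
#' 1,000 trials, each drawing 80% of the candidate features (without
#' replacement) and 80% of the samples (with replacement) -- and reports
#' the frequency with which each feature is selected. Frequent selection
#' under resampling marks a feature as informative even when collinearity
#' makes any single model's choice arbitrary.
#'
#' @inheritParams two_loop_cv
#' @return List of class `importance_table`: `frequency` (named, selected
#'   count / `n_boot` for every original feature), `n_boot`, `failures`.
#'   More than 10% failed trials is an error.
#' @export
bootstrap_importance <- function(features, outcomes,
                                 config = selection_config()) {
  x <- as_design(features)
  n <- nrow(x); p <- ncol(x)
  counts <- stats::setNames(numeric(p), colnames(x))
  failures <- 0L
  n_feat <- max(1L, floor(config$boot_feature_frac * p))
  n_samp <- max(2L, round(config$boot_sample_frac * n))
  for (b in seq_len(config$n_boot)) {
    bseed <- child_seed(config$seed, paste0("boot", b))
    draw <- with_seed(bseed, list(
      cols = sample.int(p, n_feat),
      rows = sample.int(n, n_samp, replace = TRUE)))
    xb <- x[draw$rows, draw$cols, drop = FALSE]
    outb <- outcomes[draw$rows, , drop = FALSE]
    sel <- tryCatch({
      mu <- colMeans(xb); sg <- apply(xb, 2L, stats::sd)
      keep <- sg > 0
      zb <- scale(xb[, keep, drop = FALSE], mu[keep], sg[keep])
      pr <- prune_collinear(zb, config$corr_threshold,
                            seed = child_seed(bseed, "prune"))
      stepwise_l0(pr$x, outb, inner_scheme = config$inner_scheme,
                  inner_folds = config$inner_folds, max_k = config$max_k,
                  seed = child_seed(bseed, "inner"))$selected
    }, evorisk_error = function(e) NULL, error = function(e) NULL)
    if (is.null(sel)) failures <- failures + 1L
    else counts[sel] <- counts[sel] + 1L
  }
  if (failures > 0.1 * config$n_boot)
    abort_evorisk(sprintf("%d of %d bootstrap trials failed", failures,
                          config$n_boot), "evorisk_selection_error")
  structure(list(frequency = counts / config$n_boot,
                 n_boot = config$n_boot, failures = failures),
            class = "importance_table")
}

#' Permutation control for the two-loop pipeline
#'
#' Breaks the feature-outcome link by permuting every feature column
#' across samples with a seeded permutation (outcomes untouched), then
#' runs [two_loop_cv()] unchanged. On genuinely predictive data the
#' permuted run should score at chance (CI near 0.5) with visibly larger
#' spread than the unpermuted run.
#'
#' @inheritParams two_loop_cv
#' @param perms Optional list of permutations (one integer vector per
#'   column, in column order); defaults to independent seeded draws.
#'   Passing identity permutations reproduces the unpermuted run exactly.
#' @return A `cv_result`, plus element `perms` recording the permutations.
#' @export
permutation_control <- function(features, outcomes,
                                config = selection_config(),
                                model = c("l0", "lasso"), perms = NULL) {
  x <- as_design(features)
  n <- nrow(x)
  if (is.null(perms)) {
    perms <- lapply(seq_len(ncol(x)), function(j) {
      with_seed(child_seed(config$seed, paste0("perm", j)), sample.int(n))
    })
  }
  xp <- x
  for (j in seq_len(ncol(x))) xp[, j] <- x[perms[[j]], j]
  fm <- feature_matrix(xp, if (inherits(features, "feature_matrix"))
    features$classes else
      stats::setNames(rep("evolutionary", ncol(x)), colnames(x)))
  res <- two_loop_cv(fm, outcomes, config, model = match.arg(model))
  res$perms <- perms
  res
}

#' Pairwise correlation landscape with Ward ordering
#'
#' Full Pearson correlation matrix over features plus the display ordering
#' given by agglomerative Ward clustering on the correlation-derived
#' distance `1 - r`. Zero-variance features have undefined correlation and
#' are reported as excluded.
#'
#' @param features Matrix or [feature_matrix()].
#' @return List with `cor`, `order` (feature names in dendrogram order),
#'   `hclust`, `excluded`.
#' @export
correlation_landscape <- function(features) {
  x <- as_design(features)
  if (ncol(x) < 2L)
    abort_evorisk("need at least two features", "evorisk_validation_error")
  zero_var <- apply(x, 2L, stats::sd) == 0
  xs <- x[, !zero_var, drop = FALSE]
  cc <- stats::cor(xs)
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "ward.D2")
  list(cor = cc, order = colnames(xs)[hc$order], hclust = hc,
       excluded = colnames(x)[zero_var])
}
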