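test_that("collinearity pruning drops one of each highly correlated pair", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "z")))
  x[, "b"] <- x[, "a"]                      # r = 1 duplicate
  x[, "z"] <- 0                             # zero variance
  pr <- prune_collinear(x, threshold = 0.8, seed = 1)
  expect_true("z" %in% pr$dropped)
  expect_equal(sum(c("a", "b") %in% colnames(pr$x)), 1L)
  expect_true("c" %in% colnames(pr$x))
  # moderate correlation survives the default threshold
  set.seed(4)
  u <- rnorm(400)
  y <- cbind(p = u, q = 0.5 * u + sqrt(1 - 0.25) * rnorm(400))
  expect_lt(abs(stats::cor(y)[1, 2]), 0.8)
  pr2 <- prune_collinear(y, threshold = 0.8, seed = 1)
  expect_equal(ncol(pr2$x), 2L)
  # seeded coin flips make the survivor deterministic
  pr3 <- prune_collinear(x, threshold = 0.8, seed = 1)
  expect_identical(colnames(pr$x), colnames(pr3$x))
})

test_that("step-wise selection prefers dominant features and never regresses", {
  s <- toy_surv(120, beta = c(1.5, 0), seed = 8)
  colnames(s$X) <- c("signal", "noise")
  sel <- stepwise_l0(s$X, s$outcomes, max_k = 2, seed = 1)
  expect_identical(sel$selected[1], "signal")
  expect_true(all(diff(sel$trace) > 0) || length(sel$trace) <= 1)
})

test_that("step-wise selection recovers planted hazardous features", {
  hits <- 0L
  runs <- 50L
  for (r in seq_len(runs)) {
    set.seed(1000 + r)
    n <- 120; p <- 30
    X <- matrix(rnorm(n * p), n,
                dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
    eta <- X[, 1] * 1.2 + X[, 2] * 1.1 + X[, 3] * 1.0
    tt <- rexp(n, 0.05 * exp(eta)); cc <- runif(n, 5, 60)
    o <- survival_records(rownames(X), pmin(tt, cc), as.numeric(tt <= cc))
    sel <- stepwise_l0(X, o, max_k = 6, seed = r)
    if (sum(c("f1", "f2", "f3") %in% sel$selected) >= 2) hits <- hits + 1L
  }
  expect_gte(hits / runs, 0.8)
})

test_that("two-loop CV bookkeeping and determinism hold", {
  fx <- shared_features()
  cfg <- selection_config(outer_repeats = 2, max_k = 3, seed = 11)
  res <- two_loop_cv(fx$features, fx$outcomes, cfg)
  # each sample is held out exactly once per replicate
  tab <- table(res$predictions$sample, res$predictions$replicate)
  expect_true(all(tab == 1))
  expect_equal(nrow(res$predictions),
               nrow(fx$features$x) * cfg$outer_repeats)
  expect_length(res$ci, cfg$outer_repeats)
  res2 <- two_loop_cv(fx$features, fx$outcomes, cfg)
  expect_identical(res$predictions$eta, res2$predictions$eta)
  expect_identical(res$selected, res2$selected)
})

test_that("the leakage canary is never selected and CI stays at chance on noise", {
  set.seed(77)
  n <- 90
  X <- matrix(rnorm(n * 6), n,
              dimnames = list(paste0("s", 1:n), paste0("n", 1:6)))
  o <- survival_records(rownames(X), rexp(n, 0.05), rbinom(n, 1, 0.7))
  # plant the event indicator as a column; training rows are overwritten
  # with noise inside the CV, so selecting it would prove leakage
  X[, "n6"] <- o$event
  fm <- feature_matrix(X, stats::setNames(rep("evolutionary", 6),
                                          colnames(X)))
  cfg <- selection_config(outer_repeats = 3, max_k = 3, seed = 5)
  res <- two_loop_cv(fm, o, cfg, canary = "n6")
  expect_false(any(vapply(res$selected, function(s) "n6" %in% s,
                          logical(1))))
  # pure-noise design scores at chance
  expect_lt(abs(res$ci_mean - 0.5), 0.1)
})

test_that("identity permutations reproduce the unpermuted run exactly", {
  fx <- shared_features()
  keep <- subset_classes(fx$features, "clinical")
  cfg <- selection_config(outer_repeats = 2, max_k = 2, seed = 9)
  plain <- two_loop_cv(keep, fx$outcomes, cfg)
  n <- nrow(keep$x)
  perm <- permutation_control(keep, fx$outcomes, cfg,
                              perms = rep(list(seq_len(n)), ncol(keep$x)))
  expect_identical(plain$predictions$eta, perm$predictions$eta)
  expect_identical(plain$ci, perm$ci)
})

test_that("bootstrap importance flags informative features", {
  s <- toy_surv(150, beta = c(1.3, rep(0, 9)), seed = 14)
  colnames(s$X) <- c("signal", paste0("noise", 1:8), "flat")
  s$X[, "flat"] <- 1                       # zero variance: never selectable
  fm <- feature_matrix(s$X, stats::setNames(rep("evolutionary", 10),
                                            colnames(s$X)))
  cfg <- selection_config(n_boot = 40, max_k = 3, seed = 4)
  imp <- bootstrap_importance(fm, s$outcomes, cfg)
  expect_length(imp$frequency, 10L)
  expect_true(all(imp$frequency >= 0 & imp$frequency <= 1))
  expect_equal(unname(imp$frequency["flat"]), 0)
  expect_identical(names(which.max(imp$frequency)), "signal")
  expect_identical(imp$n_boot, 40L)
})

test_that("the protocol defaults match the published analysis settings", {
  cfg <- selection_config()
  expect_identical(cfg$n_boot, 1000L)
  expect_equal(cfg$boot_feature_frac, 0.8)
  expect_equal(cfg$boot_sample_frac, 0.8)
  expect_identical(cfg$outer_folds, 3L)
  expect_identical(cfg$outer_repeats, 5L)
  expect_identical(cfg$inner_folds, 3L)
  expect_true(cfg$inner_scheme %in% c("kfold", "loocv"))
  expect_equal(cfg$corr_threshold, 0.8)
  expect_setequal(cfg$lambda_grid, c(0.03, 0.1, 0.3, 1, 3, 10, 30))
})

test_that("LOOCV inner scheme works on a small cohort", {
  s <- toy_surv(36, beta = c(1.2, 0), seed = 19)
  sel <- stepwise_l0(s$X, s$outcomes, inner_scheme = "loocv", max_k = 2,
                     seed = 2)
  expect_identical(sel$selected[1], "f1")
})

test_that("l0 step-wise beats or ties lasso on the standard benchmark", {
  s <- toy_surv(180, beta = c(0.9, 0.7, 0.5, rep(0, 12)), seed = 100)
  fm <- feature_matrix(s$X, stats::setNames(rep("evolutionary", 15),
                                            colnames(s$X)))
  cfg <- selection_config(outer_repeats = 3, max_k = 5, seed = 100)
  ci_l0 <- two_loop_cv(fm, s$outcomes, cfg, model = "l0")$ci_mean
  ci_lasso <- two_loop_cv(fm, s$outcomes, cfg, model = "lasso")$ci_mean
  expect_gte(ci_l0, ci_lasso - 0.01)
})

test_that("the correlation landscape groups planted blocks contiguously", {
  set.seed(6)
  n <- 120
  u <- rnorm(n); v <- rnorm(n)
  x <- cbind(a1 = u + 0.1 * rnorm(n), a2 = u + 0.1 * rnorm(n),
             a3 = u + 0.1 * rnorm(n),
             b1 = v + 0.1 * rnorm(n), b2 = v + 0.1 * rnorm(n),
             b3 = v + 0.1 * rnorm(n))
  cl <- correlation_landscape(x)
  ord <- cl$order
  blk_a <- range(match(c("a1", "a2", "a3"), ord))
  blk_b <- range(match(c("b1", "b2", "b3"), ord))
  expect_equal(diff(blk_a), 2L)
  expect_equal(diff(blk_b), 2L)
  # duplicated feature and negation hit the correlation extremes
  x2 <- cbind(x[, 1:2], dup = x[, 1], neg = -x[, 1])
  colnames(x2)[1] <- "orig"
  cl2 <- correlation_landscape(x2)
  expect_equal(cl2$cor["orig", "dup"], 1)
  expect_equal(cl2$cor["orig", "neg"], -1)
  # zero-variance features are excluded, not silently correlated
  x3 <- cbind(x, flat = rep(1, n))
  expect_identical(correlation_landscape(x3)$excluded, "flat")
})
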