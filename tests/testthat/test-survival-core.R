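test_that("the partial likelihood at beta = 0 is the log risk-set sum", {
  X3 <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "f"))
  o3 <- survival_records(c("a", "b", "c"), c(1, 2, 3), c(1, 1, 1))
  expect_equal(cox_nll(0, X3, o3)$nll, log(3) + log(2))
  o2 <- survival_records(c("a", "b"), c(1, 2), c(1, 1))
  expect_equal(cox_nll(0, matrix(0, 2, 1), o2)$nll, log(2))
  # random censored instance vs the independent oracle
  s <- toy_surv(40, seed = 5)
  expect_equal(cox_nll(c(0, 0), s$X, s$outcomes)$nll, nll0_oracle(s$outcomes))
  # all-censored cohorts have no likelihood
  oc <- survival_records(c("a", "b"), c(1, 2), c(0, 0))
  expect_error(cox_nll(0, matrix(0, 2, 1), oc),
               class = "evorisk_degenerate_error")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(21)
  X <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("s", 1:5), NULL))
  o <- survival_records(paste0("s", 1:5), c(2, 5, 1, 7, 3), c(1, 0, 1, 1, 1))
  beta <- rnorm(3)
  got <- cox_nll(beta, X, o)$grad
  h <- 1e-6
  fd <- vapply(1:3, function(j) {
    e <- numeric(3); e[j] <- h
    (cox_nll(beta + e, X, o)$nll - cox_nll(beta - e, X, o)$nll) / (2 * h)
  }, numeric(1))
  expect_equal(unname(got), fd, tolerance = 1e-6)
})

test_that("unpenalized fits agree with the survival-package oracle", {
  skip_if_not_installed("survival")
  s <- toy_surv(300, beta = c(0.8, -0.5), seed = 2)
  fit <- cox_fit(s$X, s$outcomes)
  expect_true(fit$converged)
  oracle <- survival::coxph(
    survival::Surv(s$outcomes$time, s$outcomes$event) ~ s$X,
    ties = "breslow")
  # sign convention: this package's hazard is exp(-beta'X)
  expect_equal(unname(fit$coef), unname(-stats::coef(oracle)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(stats::vcov(oracle)))), tolerance = 1e-5)
})

test_that("separation is flagged, not silently returned", {
  # group 1 always fails first: likelihood maximized at infinite coefficient
  X <- matrix(c(rep(1, 5), rep(0, 5)), 10, 1,
              dimnames = list(paste0("s", 1:10), "g"))
  o <- survival_records(paste0("s", 1:10), c(1:5, 11:15), rep(1, 10))
  fit <- cox_fit(X, o)
  expect_false(fit$converged)
  expect_identical(fit$flag, "separation")
})

test_that("a large enough l1 penalty shrinks every coefficient to zero", {
  s <- toy_surv(100, seed = 3)
  g0 <- cox_nll(c(0, 0), s$X, s$outcomes)$grad
  fit <- cox_fit(s$X, s$outcomes, lambda = 10 * max(abs(g0)))
  expect_true(fit$converged)
  expect_identical(unname(fit$coef), c(0, 0))
  # moderate penalty shrinks relative to the unpenalized fit
  f_free <- cox_fit(s$X, s$outcomes)
  f_pen <- cox_fit(s$X, s$outcomes, lambda = 2)
  expect_true(all(abs(f_pen$coef) <= abs(f_free$coef) + 1e-6))
})

test_that("coefficient recovery lands within 3 SE at n = 2000", {
  s <- toy_surv(2000, beta = c(0.7, -0.4), seed = 17)
  fit <- cox_fit(s$X, s$outcomes)
  # generator hazard is exp(+X beta); package convention is exp(-beta'X)
  expect_true(all(abs(fit$coef - c(-0.7, 0.4)) < 3 * fit$se))
})

test_that("concordance follows its definition exactly", {
  # perfectly reversed ranking, all events
  o <- survival_records(1:4, c(1, 2, 3, 4), rep(1, 4))
  expect_equal(concordance_index(c(4, 3, 2, 1), o), 1)
  # hand-enumerated: 3 comparable pairs, 2 concordant
  o3 <- survival_records(1:3, c(1, 2, 3), rep(1, 3))
  expect_equal(concordance_index(c(3, 1, 2), o3), 2 / 3)
  # ties in risk score contribute nothing to the numerator
  expect_equal(concordance_index(c(1, 1, 1), o3), 0)
  expect_error(concordance_index(c(1, 2), survival_records(1:2, c(3, 3),
                                                           c(1, 1))),
               class = "evorisk_degenerate_error")
})

test_that("concordance matches brute force on 200 random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    y <- round(stats::rexp(n, 0.1), 1) + 0.1   # induce occasional ties
    d <- stats::rbinom(n, 1, 0.7)
    eta <- round(stats::rnorm(n), 1)
    if (sum(d) == 0 || max(y) == min(y)) next
    o <- survival_records(seq_len(n), y, d)
    den <- sum(vapply(which(d == 1), function(k) sum(y > y[k]), numeric(1)))
    if (den == 0) next
    expect_equal(concordance_index(eta, o), ci_bruteforce(eta, o))
  }
})

test_that("concordance is invariant under monotone transforms of the score", {
  s <- toy_surv(150, seed = 23)
  eta <- s$eta
  base <- concordance_index(eta, s$outcomes)
  expect_equal(concordance_index(3 * eta + 7, s$outcomes), base)
  expect_equal(concordance_index(exp(eta), s$outcomes), base)
})

test_that("the logrank test matches hand computation and the oracle", {
  # A = {1, 3}, B = {2, 4}, all events: z^2 = 8/13
  o <- survival_records(1:4, c(1, 2, 3, 4), rep(1, 4))
  lr <- logrank_test(c("A", "B", "A", "B"), o)
  expect_equal(lr$z2, 8 / 13, tolerance = 1e-12)
  # identical groups: statistic 0, p = 1
  o2 <- survival_records(1:6, rep(c(1, 2, 3), 2), rep(1, 6))
  lr2 <- logrank_test(rep(c("A", "B"), each = 3), o2)
  expect_equal(lr2$z2, 0)
  expect_equal(lr2$p, 1)
  # label swap leaves the statistic unchanged
  s <- toy_surv(80, seed = 31)
  grp <- rep(c(TRUE, FALSE), 40)
  expect_equal(logrank_test(grp, s$outcomes)$z2,
               logrank_test(!grp, s$outcomes)$z2)
  # one group's events all strictly precede the other's
  big <- survival_records(1:200, c(1:100, 201:300), rep(1, 200))
  expect_lt(logrank_test(rep(c(1, 2), each = 100), big)$p, 0.001)
  expect_error(logrank_test(grp[1:4],
                            survival_records(1:4, 1:4, rep(0, 4))),
               class = "evorisk_degenerate_error")
})

test_that("logrank agrees with survival::survdiff on random data", {
  skip_if_not_installed("survival")
  set.seed(5)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    y <- round(stats::rexp(n, 0.1), 1) + 0.1
    d <- stats::rbinom(n, 1, 0.6)
    g <- stats::rbinom(n, 1, 0.5)
    if (sum(d) == 0 || length(unique(g)) < 2) next
    o <- survival_records(seq_len(n), y, d)
    sd <- survival::survdiff(survival::Surv(y, d) ~ g)
    expect_equal(logrank_test(g, o)$z2, unname(sd$chisq), tolerance = 1e-8)
  }
})

test_that("the product-limit estimator handles censoring correctly", {
  # all censored: flat at 1
  oc <- survival_records(1:3, c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(km_curve(oc)), 0L)
  # 1 (event), 2 (censored), 3 (event): S = 2/3 after t=1, 0 after t=3
  o <- survival_records(1:3, c(1, 2, 3), c(1, 0, 1))
  km <- km_curve(o)
  expect_equal(km$surv, c(2 / 3, 0))
  # without censoring: S after k-th event = (n-k)/n
  n <- 12
  oe <- survival_records(1:n, seq_len(n), rep(1, n))
  expect_equal(km_curve(oe)$surv, (n - seq_len(n)) / n)
  # survival-package oracle on a censored instance
  skip_if_not_installed("survival")
  s <- toy_surv(60, seed = 41)
  km2 <- km_curve(s$outcomes)
  sf <- survival::survfit(survival::Surv(s$outcomes$time,
                                         s$outcomes$event) ~ 1)
  expect_equal(km2$surv, summary(sf)$surv, tolerance = 1e-12)
})

test_that("a merged cohort's KM curve lies between the group curves", {
  s <- toy_surv(100, seed = 51)
  grp <- s$eta > stats::median(s$eta)
  km_all <- km_curve(s$outcomes)
  km_hi <- km_curve(s$outcomes[grp, ])
  km_lo <- km_curve(s$outcomes[!grp, ])
  surv_at <- function(km, t) {
    if (!nrow(km) || t < km$time[1]) return(1)
    km$surv[max(which(km$time <= t))]
  }
  for (t in km_all$time) {
    lo <- min(surv_at(km_hi, t), surv_at(km_lo, t))
    hi <- max(surv_at(km_hi, t), surv_at(km_lo, t))
    expect_gte(surv_at(km_all, t), lo - 1e-12)
    expect_lte(surv_at(km_all, t), hi + 1e-12)
  }
})

test_that("risk scores follow eta = -beta'X and models serialize", {
  s <- toy_surv(50, seed = 6)
  fit <- cox_fit(s$X, s$outcomes)
  eta <- risk_scores(fit, s$X)
  expect_equal(unname(eta), as.vector(-s$X %*% fit$coef))
  # raising a covariate with negative beta raises eta
  j <- which(fit$coef < 0)[1]
  X2 <- s$X; X2[, j] <- X2[, j] + 1
  expect_true(all(risk_scores(fit, X2) > eta))
  path <- withr::local_tempfile(fileext = ".json")
  write_cox_model(fit, path)
  back <- read_cox_model(path)
  expect_equal(back$coef, fit$coef)
})
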