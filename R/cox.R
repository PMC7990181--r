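# Breslow-approximation partial-likelihood internals. The package-wide sign
# convention follows the hazard parameterization h_i(t) = h(t) exp(-b'X_i),
# so the per-sample linear predictor is lp = -X b and the risk score eta
# equals lp: larger eta, larger hazard.

# Sort once per fit; all likelihood evaluations then run on the sorted
# arrays with a single cumulative sum over a reversed column block.
cox_prepare <- function(X, time, event, need_hess = TRUE) {
  ord <- order(time)
  t_s <- time[ord]
  d <- event[ord]
  ev <- which(d == 1)
  if (!length(ev))
    abort_evorisk("all samples censored: partial likelihood is degenerate",
                  "evorisk_degenerate_error")
  n <- length(t_s)
  Xs <- X[ord, , drop = FALSE]
  p <- ncol(Xs)
  prep <- list(X = Xs, ev = ev,
               f = match(t_s, t_s),    # first index of each tie group
               ridx = n:1,
               Zg = cbind(1, Xs))
  if (need_hess) {
    pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
    prep$pr <- pr
    prep$Zh <- cbind(prep$Zg, Xs[, pr[, 1L], drop = FALSE] *
                       Xs[, pr[, 2L], drop = FALSE])
  }
  prep
}

# mode: "nll" (value only, cheap line-search path), "grad", or "hess".
cox_eval <- function(beta, prep, mode = "grad") {
  X <- prep$X; ev <- prep$ev; f <- prep$f; ridx <- prep$ridx
  p <- ncol(X)
  lp <- as.vector(X %*% (-beta))
  m <- max(lp)
  w <- exp(lp - m)
  if (mode == "nll") {
    rc0 <- cumsum(w[ridx])[ridx]
    return(list(nll = sum(log(rc0[f[ev]]) + m - lp[ev])))
  }
  pr <- prep$pr
  blocks <- (if (mode == "hess") prep$Zh else prep$Zg) * w
  rc <- blocks[ridx, , drop = FALSE]
  for (j in seq_len(ncol(rc))) rc[, j] <- cumsum(rc[, j])
  rc <- rc[ridx, , drop = FALSE]
  S0 <- rc[f[ev], 1L]
  out <- list(nll = sum(log(S0) + m - lp[ev]))
  Sratio <- rc[f[ev], 1L + seq_len(p), drop = FALSE] / S0
  out$grad <- colSums(X[ev, , drop = FALSE] - Sratio)
  if (mode == "hess") {
    H <- matrix(0, p, p)
    vals <- colSums(rc[f[ev], -(1:(p + 1L)), drop = FALSE] / S0) -
      colSums(Sratio[, pr[, 1L], drop = FALSE] *
                Sratio[, pr[, 2L], drop = FALSE])
    H[upper.tri(H, diag = TRUE)] <- vals
    H <- H + t(H) - diag(diag(H), p)
    out$hessian <- H
  }
  out
}

cox_parts <- function(beta, X, time, event, hessian = FALSE) {
  prep <- cox_prepare(X, time, event, need_hess = hessian)
  cox_eval(beta, prep, mode = if (hessian) "hess" else "grad")
}

as_design <- function(features) {
  if (inherits(features, "feature_matrix")) features$x
  else as.matrix(features)
}

#' Negative log-partial likelihood of the Cox model
#'
#' Evaluates the Breslow-approximation negative log-partial likelihood and
#' its gradient under the package's sign convention (hazard proportional
#' to `exp(-beta'X)`). At `beta = 0` the value reduces to the sum over
#' events of the log risk-set size.
#'
#' @param beta Coefficient vector (length `ncol(features)`).
#' @param features Feature matrix or [feature_matrix()] aligned with
#'   `outcomes`.
#' @param outcomes A `survival_records` table.
#' @return List with elements `nll` (scalar) and `grad`.
#' @export
cox_nll <- function(beta, features, outcomes) {
  X <- as_design(features)
  parts <- cox_parts(beta, X, outcomes$time, outcomes$event)
  list(nll = parts$nll, grad = parts$grad)
}

#' Fit a Cox proportional-hazards model
#'
#' Unpenalized fits (`lambda = 0`) use Newton's method with step-halving on
#' the Breslow negative log-partial likelihood (convergence when the
#' likelihood changes by less than `tol`); `lambda > 0` adds an l1 penalty
#' `lambda * sum(|beta|)` solved by proximal-gradient iteration with
#' backtracking. Non-convergence and separation (coefficients diverging,
#' as when one group's events all precede the other's) are flagged on the
#' returned model rather than silently ignored.
#'
#' @inheritParams cox_nll
#' @param lambda l1 penalty weight, `>= 0`.
#' @param tol Convergence tolerance on the objective change (`1e-7`
#'   unpenalized, `1e-6` lasso).
#' @param max_iter Iteration cap.
#' @return A `cox_model`: list with `coef` (named), `se` (unpenalized fits
#'   only), `nll`, `lambda`, `converged`, `flag`, `iterations`.
#' @export
cox_fit <- function(features, outcomes, lambda = 0,
                    tol = if (lambda > 0) 1e-6 else 1e-7, max_iter = 500L) {
  X <- as_design(features)
  stopifnot(ncol(X) >= 1L, nrow(X) == nrow(outcomes))
  time <- outcomes$time; event <- outcomes$event
  p <- ncol(X)
  beta <- numeric(p)
  flag <- NA_character_
  converged <- FALSE
  se <- rep(NA_real_, p)
  prep <- cox_prepare(X, time, event, need_hess = lambda == 0)
  if (lambda == 0) {
    cur <- cox_eval(beta, prep, mode = "hess")
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      H <- cur$hessian + diag(1e-9, p)
      dir <- tryCatch(solve(H, -cur$grad), error = function(e) NULL)
      if (is.null(dir)) { flag <- "singular_hessian"; break }
      step <- 1
      repeat {
        cand <- beta + step * dir
        nxt <- cox_eval(cand, prep, mode = "nll")
        if (is.finite(nxt$nll) && nxt$nll <= cur$nll) break
        step <- step / 2
        if (step < 1e-10) { nxt <- NULL; break }
      }
      if (is.null(nxt)) { flag <- "no_descent"; break }
      delta <- cur$nll - nxt$nll
      beta <- cand
      cur <- cox_eval(beta, prep, mode = "hess")
      if (max(abs(beta)) > 15) { flag <- "separation"; break }
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged && is.na(flag)) flag <- "max_iter"
    if (converged) {
      cov <- tryCatch(solve(cur$hessian), error = function(e) NULL)
      if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
    }
    nll <- cur$nll
  } else {
    soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
    cur <- cox_eval(beta, prep, mode = "grad")
    step <- 1
    iter <- 0L
    while (iter < max_iter * 4L) {
      iter <- iter + 1L
      repeat {
        cand <- soft(beta - step * cur$grad, step * lambda)
        nxt <- cox_eval(cand, prep, mode = "nll")
        dlt <- cand - beta
        if (is.finite(nxt$nll) &&
            nxt$nll <= cur$nll + sum(cur$grad * dlt) +
              sum(dlt^2) / (2 * step)) break
        step <- step / 2
        if (step < 1e-12) { nxt <- NULL; break }
      }
      if (is.null(nxt)) { flag <- "no_descent"; break }
      obj_old <- cur$nll + lambda * sum(abs(beta))
      beta <- cand
      cur <- cox_eval(beta, prep, mode = "grad")
      delta <- obj_old - (cur$nll + lambda * sum(abs(beta)))
      if (max(abs(beta)) > 15) { flag <- "separation"; break }
      if (abs(delta) < tol) { converged <- TRUE; break }
      step <- min(step * 2, 1)
    }
    if (!converged && is.na(flag)) flag <- "max_iter"
    nll <- cur$nll
  }
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 nll = nll, lambda = lambda, converged = converged,
                 flag = flag, iterations = NULL),
            class = "cox_model")
}

#' Risk scores of a fitted model
#'
#' Risk scores follow `eta = -beta'X`, the log of the parametric part of
#' the hazard: a larger score means a larger predicted hazard, so ranking
#' by `eta` ranks patients worst-first.
#'
#' @param model A `cox_model`.
#' @param features Matrix or `feature_matrix` whose columns include the
#'   model's features.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_scores <- function(model, features) {
  X <- as_design(features)[, names(model$coef), drop = FALSE]
  stats::setNames(as.vector(-X %*% model$coef), rownames(X))
}

#' Serialize / restore a Cox model
#' @param model A `cox_model`.
#' @param path JSON path.
#' @return `path` (write) or the restored `cox_model` (read).
#' @export
write_cox_model <- function(model, path) {
  jsonlite::write_json(list(coef = as.list(model$coef),
                            lambda = model$lambda,
                            converged = model$converged,
                            flag = model$flag),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cox_model
#' @export
read_cox_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coef = unlist(x$coef), se = NULL, nll = NA_real_,
                 lambda = x$lambda, converged = x$converged,
                 flag = if (is.null(x$flag)) NA_character_ else x$flag),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("Cox model (lambda=%g, %s)\n", x$lambda,
              if (isTRUE(x$converged)) "converged" else
                paste0("NOT converged: ", x$flag)))
  print(round(x$coef, 4))
  invisible(x)
}
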