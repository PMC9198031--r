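#' U-statistic (Hajek-projection) sandwich variance
#'
#' Pair contributions to the pairwise score are not independent — every
#' subject appears in many pairs — so the model-based inverse Hessian
#' understates the variance.  The sandwich is `A^{-1} B A^{-1}` with
#' `A = -sum_k H_k(beta_hat)` and
#'
#' \deqn{B = \sum_{i \in cases} U_i U_i^\top
#'         + \sum_{j \in controls} U_j U_j^\top
#'         - \sum_{pairs} s_m s_m^\top}
#'
#' where `U_i` aggregates the score contributions of all pairs containing
#' subject i (within its site) and `s_m` is one pair's score contribution.
#' The subtracted term removes the per-pair variance that the two
#' per-subject sums count twice; with it, the estimator has the correct
#' two-sample U-statistic projection asymptotics and reduces exactly to the
#' classical robust conditional-logistic form `A^{-1} (sum_m s_m s_m') A^{-1}`
#' on 1:1 matched pairs.  When pair scores are (approximately) independent,
#' `B ~ A` and the sandwich collapses to the model-based `A^{-1}`.
#'
#' @param fit A converged `dclr_fit` (any method).
#' @param sites The site data the fit was computed from.
#' @return Symmetric positive semidefinite p x p matrix.
#' @export
sandwich_variance <- function(fit, sites) {
  stopifnot(inherits(fit, "dclr_fit"))
  if (!isTRUE(fit$converged))
    stop("sandwich variance requires a converged fit")
  sites <- as_site_list(sites)
  beta <- as.numeric(fit$beta_hat)
  p <- length(beta)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (s in sites) {
    if (site_n_pairs(s) < 1) next
    sp <- site_split(s)
    A <- A - pair_eval_cpp(sp$Xcase, sp$Xctrl, beta, 2L)$hess
    sw <- pair_sandwich_cpp(sp$Xcase, sp$Xctrl, beta)
    B <- B + crossprod(sw$Ucase) + crossprod(sw$Uctrl) - sw$pair_outer
  }
  kap <- tryCatch(kappa(A, exact = TRUE), error = function(e) Inf)
  Ainv <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(Ainv) || !is.finite(kap) || kap > 1e12)
    stop(sprintf(
      "aggregated information matrix is singular (condition number %.3g)",
      kap))
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(fit$beta_hat), names(fit$beta_hat))
  V
}

#' Within-site percentile bootstrap confidence intervals
#'
#' Resamples subjects with replacement within each site (preserving the
#' multi-site structure and the site-specific baseline risks), refits the
#' requested estimator, and returns percentile intervals.  A replicate in
#' which the refit is inestimable (e.g. a rare-event site loses all its
#' cases and every site follows) is redrawn up to 10 times, then skipped
#' and counted.
#'
#' @param sites List of [site_data()] objects (or a `multisite_data`).
#' @param fit_method `"pooled"`, `"dclr"`, or `"meta"`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed; the same seed yields bit-identical intervals.
#' @param level Confidence level (default 0.95).
#' @param ... Passed to the underlying fitting function.
#' @return A `dclr_bootstrap` list: `ci` (p x 2), `estimates`
#'   (n_boot x p), `n_skipped`, `level`, `fit_method`.
#' @export
bootstrap_ci <- function(sites, fit_method = c("pooled", "dclr", "meta"),
                         n_boot = 100L, seed = 1L, level = 0.95, ...) {
  fit_method <- match.arg(fit_method)
  sites <- as_site_list(sites)
  stopifnot(n_boot >= 1)
  fitter <- switch(fit_method,
    pooled = function(ss) coef(fit_pooled(ss, ...)),
    dclr = function(ss) coef(fit_dclr(ss, ...)),
    meta = function(ss) coef(fit_meta(lapply(ss, function(s)
      tryCatch(fit_local(s), error = function(e) NULL)))))
  p <- ncol(sites[[1]]$X)
  stream <- make_stream_seed(seed)
  est <- matrix(NA_real_, n_boot, p,
                dimnames = list(NULL, colnames(sites[[1]]$X)))
  n_skipped <- 0L
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old), add = TRUE)
  assign(".Random.seed", stream, envir = globalenv())
  for (b in seq_len(n_boot)) {
    fit_b <- NULL
    for (attempt in 1:10) {
      res <- lapply(sites, function(s) {
        idx <- sample.int(length(s$y), replace = TRUE)
        site_data(s$site_id, s$y[idx], s$X[idx, , drop = FALSE])
      })
      fit_b <- tryCatch(fitter(res), error = function(e) NULL)
      if (!is.null(fit_b)) break
    }
    if (is.null(fit_b)) n_skipped <- n_skipped + 1L else est[b, ] <- fit_b
  }
  keep <- est[complete.cases(est), , drop = FALSE]
  if (nrow(keep) == 0) stop("every bootstrap replicate was inestimable")
  alpha <- (1 - level) / 2
  ci <- t(apply(keep, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  structure(list(ci = ci, estimates = keep, n_skipped = n_skipped,
                 level = level, fit_method = fit_method, seed = seed),
            class = "dclr_bootstrap")
}

#' @export
print.dclr_bootstrap <- function(x, ...) {
  cat(sprintf("Within-site bootstrap (%s, %d replicates kept, %d skipped)\n",
              x$fit_method, nrow(x$estimates), x$n_skipped))
  print(round(x$ci, 4))
  invisible(x)
}
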