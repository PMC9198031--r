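new_fit_result <- function(method, beta_hat, covariance, converged,
                           n_iterations, objective = NA_real_,
                           diagnostics = list()) {
  structure(list(method = method, beta_hat = beta_hat,
                 covariance = covariance, converged = converged,
                 n_iterations = n_iterations, objective = objective,
                 diagnostics = diagnostics),
            class = "dclr_fit")
}

#' @export
print.dclr_fit <- function(x, ...) {
  cat(sprintf("Pairwise conditional logistic fit (method: %s)\n", x$method))
  se <- if (!is.null(x$covariance)) sqrt(diag(x$covariance)) else
    rep(NA_real_, length(x$beta_hat))
  tab <- cbind(estimate = x$beta_hat, se = se,
               `or` = exp(x$beta_hat))
  print(round(tab, 4))
  cat(sprintf("converged: %s (%d iterations)\n", x$converged,
              x$n_iterations))
  if (length(x$diagnostics$flags))
    cat("flags:", paste(x$diagnostics$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.dclr_fit <- function(object, ...) object$beta_hat

#' @export
vcov.dclr_fit <- function(object, ...) object$covariance

#' @export
#' @importFrom stats confint
confint.dclr_fit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$covariance))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta_hat - z * se, object$beta_hat + z * se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                             1 - (1 - level) / 2))
  rownames(ci) <- names(object$beta_hat)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

# shared model-based covariance: inverse of -(H - ridge I) at the optimum
model_covariance <- function(hess, ridge = 0) {
  A <- -hess + diag(ridge, nrow(hess))
  V <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  V <- (V + t(V)) / 2
  dimnames(V) <- dimnames(hess)
  V
}

#' Fit the pairwise conditional logistic model to one site
#'
#' Maximizes the site's pairwise log-likelihood (optionally minus a ridge
#' penalty `ridge * ||beta||^2 / 2`) by Newton's method with step halving.
#' When the unpenalized fit shows separation (coefficient norm exceeding 50
#' with a non-vanishing gradient, as happens when the few cases of a
#' rare-event site are linearly separable from its controls) the site is
#' automatically refit with `ridge = 1e-4` and flagged.
#'
#' @param data A [site_data()] object with at least one discordant pair.
#' @param ridge Nonnegative ridge penalty; default 0 (plain maximum
#'   pairwise likelihood).
#' @param tol Gradient infinity-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return A `dclr_fit` with model-based covariance (inverse negative
#'   Hessian at the optimum).
#' @examples
#' s <- site_data("A", c(1, 0, 0), cbind(x = c(0, -1, 1)))
#' coef(fit_local(s))   # symmetric pair differences force beta = 0
#' @export
fit_local <- function(data, ridge = 0, tol = 1e-8, max_iter = 100L) {
  stopifnot(is_site_data(data), ridge >= 0)
  if (site_n_pairs(data) < 1)
    stop("site '", data$site_id,
         "' is inestimable: no discordant case-control pairs")
  fit <- fit_sites_newton(list(data), ridge = ridge, tol = tol,
                          max_iter = max_iter)
  # separation: estimate diverging with a non-vanishing gradient, or a
  # perfect fit (average per-pair log-likelihood at the optimum ~ 0, i.e.
  # the cases are linearly separated from the controls)
  sep <- ridge == 0 &&
    (sqrt(sum(fit$beta^2)) > 50 || !fit$converged ||
       fit$ll / site_n_pairs(data) > -1e-6)
  flags <- fit$flags
  if (sep) {
    fit <- fit_sites_newton(list(data), ridge = 1e-4, tol = tol,
                            max_iter = max_iter)
    flags <- unique(c(flags, fit$flags, "separation_ridge_fallback"))
    ridge <- 1e-4
  }
  beta <- setNames(fit$beta, colnames(data$X))
  new_fit_result("local", beta,
                 model_covariance(fit$hess + diag(ridge, length(beta)),
                                  ridge = ridge),
                 fit$converged, fit$iter, fit$ll,
                 diagnostics = list(site_id = data$site_id,
                                    n_k = length(data$y),
                                    d_k = site_n_pairs(data),
                                    ridge = ridge,
                                    grad_norm = fit$grad_norm,
                                    flags = flags))
}

#' Pooled gold-standard estimator
#'
#' Maximizes the sum of all sites' pairwise log-likelihoods (within-site
#' pairs only, so site-specific intercepts stay eliminated) using all
#' patient-level data.  This is the benchmark the distributed estimator
#' approximates.
#'
#' @param sites A list of [site_data()] objects (or a `multisite_data`).
#' @param ridge,tol,max_iter As in [fit_local()].
#' @param start Optional starting value for the Newton iteration (the
#'   optimum of the concave objective does not depend on it; a good start
#'   just saves iterations).
#' @return A `dclr_fit` (method "pooled") with model-based covariance.
#' @export
fit_pooled <- function(sites, ridge = 0, tol = 1e-8, max_iter = 100L,
                       start = NULL) {
  sites <- as_site_list(sites)
  est <- sites[vapply(sites, site_n_pairs, numeric(1)) >= 1]
  if (length(est) == 0)
    stop("all sites are inestimable (no discordant pairs anywhere)")
  fit <- fit_sites_newton(est, ridge = ridge, tol = tol,
                          max_iter = max_iter, start = start)
  beta <- setNames(fit$beta, colnames(est[[1]]$X))
  new_fit_result("pooled", beta,
                 model_covariance(fit$hess + diag(ridge, length(beta)),
                                  ridge = ridge),
                 fit$converged, fit$iter, fit$ll,
                 diagnostics = list(
                   n_sites = length(sites),
                   n_sites_estimable = length(est),
                   excluded_sites = setdiff(
                     vapply(sites, `[[`, "", "site_id"),
                     vapply(est, `[[`, "", "site_id")),
                   grad_norm = fit$grad_norm, ridge = ridge,
                   flags = fit$flags))
}

# Newton on sum of site objectives minus ridge penalty
fit_sites_newton <- function(sites, ridge, tol, max_iter, start = NULL) {
  splits <- lapply(sites, site_split)
  p <- ncol(sites[[1]]$X)
  if (is.null(start)) start <- numeric(p)
  fn <- function(beta, order) {
    ll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
    for (sp in splits) {
      ev <- pair_eval_cpp(sp$Xcase, sp$Xctrl, beta, as.integer(order))
      ll <- ll + ev$ll
      if (order >= 1L) grad <- grad + ev$grad
      if (order >= 2L) hess <- hess + ev$hess
    }
    if (ridge > 0) {
      ll <- ll - ridge * sum(beta^2) / 2
      if (order >= 1L) grad <- grad - ridge * beta
      if (order >= 2L) hess <- hess - diag(ridge, p)
    }
    list(ll = ll, grad = grad, hess = hess)
  }
  newton_maximize(fn, start, tol = tol, max_iter = max_iter)
}

#' Fixed-effect inverse-variance meta-analysis of site fits
#'
#' Combines per-site pairwise conditional logistic estimates
#' coordinate-wise: `beta_meta_j = sum_k beta_kj / v_kj / sum_k 1 / v_kj`
#' with `v_kj` the j-th diagonal entry of site k's covariance.  Sites
#' flagged inestimable (or supplied as `NULL`) are excluded and recorded.
#'
#' The site fits are pairwise conditional logistic fits — the same family
#' as the distributed algorithm's initial step — so the comparator
#' estimates the same estimand.  Pass ordinary logistic fits (e.g. from
#' `glm`) via `beta`/`variance` extraction if the intercept-containing
#' variant is wanted.
#'
#' @param local_fits List of `dclr_fit` objects (one per site), each with a
#'   covariance.
#' @return A `dclr_fit` (method "meta") with diagonal covariance
#'   `1 / sum_k 1 / v_kj`.
#' @examples
#' # two sites, estimates 1 (variance 1) and 3 (variance 3) -> 1.5
#' @export
fit_meta <- function(local_fits) {
  local_fits <- Filter(Negate(is.null), local_fits)
  ok <- vapply(local_fits, function(f) {
    inherits(f, "dclr_fit") && !is.null(f$covariance) &&
      all(is.finite(f$beta_hat)) && all(is.finite(diag(f$covariance)))
  }, logical(1))
  excluded <- vapply(local_fits[!ok], function(f)
    as.character(f$diagnostics$site_id %||% NA_character_), character(1))
  fits <- local_fits[ok]
  if (length(fits) == 0) stop("no estimable site fits to meta-analyze")
  B <- do.call(rbind, lapply(fits, function(f) f$beta_hat))
  V <- do.call(rbind, lapply(fits, function(f) diag(as.matrix(f$covariance))))
  w <- 1 / V
  beta <- colSums(B * w) / colSums(w)
  cov <- diag(1 / colSums(w), ncol(B))
  dimnames(cov) <- list(colnames(B), colnames(B))
  new_fit_result("meta", setNames(beta, colnames(B)), cov,
                 converged = TRUE, n_iterations = 0L,
                 diagnostics = list(n_sites_used = length(fits),
                                    excluded_sites = excluded))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Anchor estimate from Step I site fits
#'
#' Averages the site-wise initial coefficient estimates into the shared
#' anchor at which every site evaluates its derivatives.  Default weights
#' are site sample sizes; inverse-variance weighting is available but can
#' be unstable when rare-event sites have near-singular local Hessians.
#'
#' @param local_fits List of `dclr_fit` objects or `dclr_initial` payloads;
#'   inestimable entries are skipped.
#' @param scheme Weighting: `"sample_size"` (default), `"inverse_variance"`
#'   (coordinate-wise), or `"unweighted"`.
#' @return Numeric anchor vector.
#' @export
initial_average <- function(local_fits,
                            scheme = c("sample_size", "inverse_variance",
                                       "unweighted")) {
  scheme <- match.arg(scheme)
  pl <- lapply(local_fits, as_initial_payload)
  pl <- Filter(function(x) isTRUE(x$estimable), pl)
  if (length(pl) == 0) stop("no estimable initial estimates to average")
  B <- do.call(rbind, lapply(pl, `[[`, "beta_hat"))
  W <- switch(scheme,
    sample_size = matrix(vapply(pl, `[[`, 0, "n_k"), nrow(B), ncol(B)),
    unweighted = matrix(1, nrow(B), ncol(B)),
    inverse_variance = {
      V <- do.call(rbind, lapply(pl, function(x) {
        if (is.null(x$var_diag)) stop(
          "inverse_variance anchor weighting needs var_diag in every payload")
        x$var_diag
      }))
      1 / V
    })
  setNames(colSums(B * W) / colSums(W), colnames(B))
}
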