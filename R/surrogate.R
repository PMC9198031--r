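#' Assemble the surrogate pairwise log-likelihood at a lead site
#'
#' The lead site holds patient-level data; every other site is represented
#' only by its derivative payload.  With per-weight-normalized site
#' objectives (weights `w_k` = pair counts `d_k` by default, so that the
#' weighted average of site gradients equals the pooled gradient divided by
#' the total pair count), the surrogate is
#'
#' \deqn{\tilde\ell(\beta) = \ell_{lead}(\beta)/w_{lead}
#'   + (\bar G - g_{lead})^\top \beta
#'   + \tfrac12 (\beta-\bar\beta)^\top (\bar H - h_{lead}) (\beta-\bar\beta)}
#'
#' where `g`/`h` are normalized gradients/Hessians at the anchor and
#' `Gbar`/`Hbar` their weighted averages across all sites.  Its gradient at
#' the anchor equals `Gbar` by construction, so maximizing it emulates
#' maximizing the pooled objective using one round of aggregates.  The
#' quadratic term is dropped for `order = "first"`.
#'
#' @param anchor Shared anchor vector (the averaged Step I estimate).
#' @param payloads List of `dclr_derivatives` payloads, one per site
#'   (including the lead), all evaluated at `anchor`.
#' @param lead The lead site's [site_data()].
#' @param order `"second"` (default; uses the Hessian correction) or
#'   `"first"`.
#' @param weight_scheme `"pair_count"` (default) or `"sample_size"`.
#' @return A `surrogate_objective` with the correction terms and an
#'   evaluator `fn(beta, order)` used by the Newton optimizer.
#' @export
build_surrogate <- function(anchor, payloads, lead,
                            order = c("second", "first"),
                            weight_scheme = c("pair_count", "sample_size")) {
  order <- match.arg(order)
  weight_scheme <- match.arg(weight_scheme)
  stopifnot(is_site_data(lead))
  validate_round(payloads, expected_anchor = anchor)
  p <- ncol(lead$X)
  anchor <- check_beta(anchor, p)
  w <- vapply(payloads, function(pay)
    switch(weight_scheme, pair_count = pay$d_k, sample_size = pay$n_k),
    numeric(1))
  if (sum(w) <= 0) stop("all surrogate weights are zero")
  Gbar <- matrix(0, p, 1); Hbar <- matrix(0, p, p)
  for (pay in payloads) {
    Gbar <- Gbar + pay$gradient
    Hbar <- Hbar + pay$hessian
  }
  Gbar <- drop(Gbar) / sum(w)
  Hbar <- Hbar / sum(w)

  lead_id <- lead$site_id
  idx <- which(vapply(payloads, `[[`, "", "site_id") == lead_id)
  if (length(idx) != 1)
    stop("lead site '", lead_id, "' must appear exactly once in payloads")
  w_lead <- w[idx]
  if (w_lead <= 0) stop("lead site '", lead_id, "' carries zero weight")
  g_lead <- payloads[[idx]]$gradient / w_lead
  h_lead <- payloads[[idx]]$hessian / w_lead

  grad_corr <- Gbar - g_lead
  hess_corr <- if (order == "second") Hbar - h_lead else matrix(0, p, p)
  sp <- site_split(lead)
  fn <- function(beta, ord = 2L) {
    ev <- pair_eval_cpp(sp$Xcase, sp$Xctrl, beta, as.integer(ord))
    db <- beta - anchor
    ll <- ev$ll / w_lead + sum(grad_corr * beta) +
      0.5 * sum(db * (hess_corr %*% db))
    out <- list(ll = ll)
    if (ord >= 1L)
      out$grad <- ev$grad / w_lead + grad_corr + drop(hess_corr %*% db)
    if (ord >= 2L) out$hess <- ev$hess / w_lead + hess_corr
    out
  }
  structure(list(anchor = anchor, lead_id = lead_id,
                 lead_loglik = function(beta)
                   pair_eval(beta, lead, 0L)$ll / w_lead,
                 grad_correction = grad_corr, hess_correction = hess_corr,
                 order = order, weight_scheme = weight_scheme,
                 w_lead = w_lead, w_total = sum(w), fn = fn),
            class = "surrogate_objective")
}

# maximize one surrogate; on non-concave corrected curvature fall back to
# the first-order surrogate (whose Hessian is the lead's, always NSD)
maximize_surrogate <- function(anchor, payloads, lead, order, weight_scheme,
                               tol = 1e-8, max_iter = 100L) {
  surr <- build_surrogate(anchor, payloads, lead, order = order,
                          weight_scheme = weight_scheme)
  fit <- newton_maximize(surr$fn, anchor, tol = tol, max_iter = max_iter)
  flags <- fit$flags
  if (order == "second") {
    ev <- eigen(surr$fn(fit$beta, 2L)$hess, symmetric = TRUE,
                only.values = TRUE)$values
    if (max(ev) > 1e-10 || !fit$converged) {
      surr <- build_surrogate(anchor, payloads, lead, order = "first",
                              weight_scheme = weight_scheme)
      fit <- newton_maximize(surr$fn, anchor, tol = tol, max_iter = max_iter)
      flags <- unique(c(flags, fit$flags, "surrogate_order_fallback"))
    }
  }
  list(fit = fit, surrogate = surr, flags = flags)
}

#' One-round distributed estimator (dCLR)
#'
#' Runs the two-step protocol: (I) every site fits its own pairwise
#' conditional logistic model and broadcasts the aggregate estimate; the
#' coordinator averages them into the anchor; (II) every site broadcasts
#' its gradient and Hessian at the anchor; a lead site assembles and
#' maximizes the surrogate objective.  Patient-level data of non-lead
#' sites are touched only through the two payload types, and exactly two
#' broadcast rounds occur (recorded in `diagnostics$communication_rounds`).
#'
#' With `lead_selection = "all_sites"` every site acts as lead in turn and
#' the per-lead surrogate estimates are synthesized by inverse-variance
#' weighted average — the recommended mode.
#'
#' @param sites List of [site_data()] objects (or a `multisite_data`).
#' @param lead_selection `"all_sites"` (default), `"max_pairs"` (single
#'   lead with the most discordant pairs), or a site id / index.
#' @param order Surrogate order, `"second"` (default) or `"first"`.
#' @param weight_scheme Site weighting inside the surrogate
#'   (`"pair_count"` default).
#' @param anchor_scheme Weighting of the Step I average, see
#'   [initial_average()].
#' @param tol,max_iter Newton convergence contract.
#' @param .payloads Optionally a precomputed `list(initial =, derivatives =,
#'   anchor =)` (used by the simulation harness to avoid refitting Step I).
#' @return A `dclr_fit` (method "dclr").
#' @export
fit_dclr <- function(sites, lead_selection = "all_sites",
                     order = c("second", "first"),
                     weight_scheme = c("pair_count", "sample_size"),
                     anchor_scheme = "sample_size",
                     tol = 1e-8, max_iter = 100L, .payloads = NULL) {
  order <- match.arg(order)
  weight_scheme <- match.arg(weight_scheme)
  sites <- as_site_list(sites)
  ids <- vapply(sites, `[[`, "", "site_id")
  if (anyDuplicated(ids)) stop("duplicate site ids")

  if (is.null(.payloads)) {
    initials <- lapply(sites, emit_initial)        # broadcast round 1
    anchor <- initial_average(initials, scheme = anchor_scheme)
    derivs <- lapply(sites, emit_derivatives, anchor = anchor) # round 2
  } else {
    initials <- .payloads$initial
    anchor <- .payloads$anchor
    derivs <- .payloads$derivatives
  }
  validate_round(derivs, expected_anchor = anchor)
  estimable <- vapply(derivs, function(d) d$d_k >= 1, logical(1))

  leads <- switch(as.character(lead_selection[1]),
    all_sites = which(estimable),
    max_pairs = which.max(vapply(derivs, `[[`, 0, "d_k")),
    {
      i <- if (lead_selection %in% ids) match(lead_selection, ids)
           else as.integer(lead_selection)
      if (is.na(i) || i < 1 || i > length(sites))
        stop("unknown lead site '", lead_selection, "'")
      if (!estimable[i]) stop("lead site '", ids[i], "' is inestimable")
      i
    })

  p <- ncol(sites[[1]]$X)
  res <- lapply(leads, function(i)
    maximize_surrogate(anchor, derivs, sites[[i]], order, weight_scheme,
                       tol = tol, max_iter = max_iter))
  ok <- vapply(res, function(r) r$fit$converged, logical(1))
  if (!any(ok)) stop("no surrogate fit converged")
  est <- lapply(res[ok], function(r) {
    V <- model_covariance(r$surrogate$w_total * r$fit$hess)
    list(beta = r$fit$beta, var = if (!is.null(V)) diag(V) else
           rep(Inf, p), cov = V, fit = r$fit, flags = r$flags,
         order = r$surrogate$order)
  })
  nm <- colnames(sites[[1]]$X)
  if (length(est) == 1L) {
    e <- est[[1]]
    beta <- setNames(e$beta, nm); cov <- e$cov
    iters <- e$fit$iter
  } else {
    B <- do.call(rbind, lapply(est, `[[`, "beta"))
    W <- do.call(rbind, lapply(est, `[[`, "var"))
    W <- 1 / W
    beta <- setNames(colSums(B * W) / colSums(W), nm)
    cov <- diag(1 / colSums(W), p)
    dimnames(cov) <- list(nm, nm)
    iters <- max(vapply(est, function(e) e$fit$iter, integer(1)))
  }
  flags <- unique(unlist(lapply(est, `[[`, "flags")))
  new_fit_result("dclr", beta, cov, converged = TRUE, n_iterations = iters,
                 diagnostics = list(
                   lead_selection = as.character(lead_selection[1]),
                   lead_sites = ids[leads][ok],
                   surrogate_order = order,
                   order_used = vapply(est, `[[`, "", "order"),
                   anchor = anchor,
                   communication_rounds = 2L,
                   n_sites = length(sites),
                   excluded_sites = ids[!estimable],
                   flags = flags))
}
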