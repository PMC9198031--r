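#' Stable log(1 + exp(x))
#'
#' Two-branch evaluation that never overflows: returns `x` for large `x`
#' and `exp(x)` for very negative `x`.  Finite for `|x|` up to at least 700.
#'
#' @param x Numeric vector.
#' @return `log(1 + exp(x))`, elementwise.
#' @export
log1pexp <- function(x) {
  out <- x # large-x branch
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

#' Build all discordant case-control pairs for one site
#'
#' Materializes the difference matrix whose row m is
#' `x(case) - x(control)` for the m-th (case, control) pair.  The number of
#' pairs is exactly `n_cases * n_controls`; a site with no cases or no
#' controls yields an empty pair set.
#'
#' For large sites the likelihood functions do not need this matrix:
#' passing the `site_data` object directly to [pairwise_loglik()] and
#' friends evaluates the pair sums in a streaming kernel with O(1) extra
#' memory, so the full set of pairs is never held at once.
#'
#' @param data A [site_data()] object.
#' @return A `pair_set` with elements `differences` (D_k x p matrix) and
#'   `d_k` (pair count).
#' @examples
#' s <- site_data("A", c(1, 0), cbind(x = c(2, 0.5)))
#' build_pairs(s)$differences # single pair, case minus control: 1.5
#' @export
build_pairs <- function(data) {
  stopifnot(is_site_data(data))
  sp <- site_split(data)
  n1 <- nrow(sp$Xcase); n0 <- nrow(sp$Xctrl)
  if (n1 == 0L || n0 == 0L) {
    diffs <- matrix(numeric(0), nrow = 0, ncol = ncol(data$X),
                    dimnames = list(NULL, colnames(data$X)))
    return(structure(list(differences = diffs, d_k = 0), class = "pair_set"))
  }
  diffs <- sp$Xcase[rep(seq_len(n1), each = n0), , drop = FALSE] -
    sp$Xctrl[rep(seq_len(n0), times = n1), , drop = FALSE]
  structure(list(differences = diffs, d_k = as.numeric(n1) * n0),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set: %d discordant pairs, p = %d>\n",
              x$d_k, ncol(x$differences)))
  invisible(x)
}

# beta' d per pair, accumulated column by column so that a column of exact
# zeros (an intercept difference) contributes literal 0.0 additions and the
# result is bit-identical under intercept shifts.
pair_linpred <- function(D, beta) {
  z <- numeric(nrow(D))
  for (l in seq_along(beta)) z <- z + beta[l] * D[, l]
  z
}

check_beta <- function(beta, p) {
  beta <- as.numeric(beta)
  if (length(beta) != p)
    stop("beta has length ", length(beta), " but the data have ", p,
         " covariates")
  if (!all(is.finite(beta))) stop("beta must be finite")
  beta
}

# Unified evaluator: order 0 = loglik, 1 = +score, 2 = +hessian.
# Accepts a site_data (streaming C kernel) or a pair_set (vectorized R path;
# the two paths cross-check each other in the test suite).
pair_eval <- function(beta, pairs, order = 2L) {
  if (is_site_data(pairs)) {
    sp <- site_split(pairs)
    beta <- check_beta(beta, ncol(pairs$X))
    ev <- pair_eval_cpp(sp$Xcase, sp$Xctrl, beta, as.integer(order))
    names(ev$grad) <- colnames(pairs$X)
    dimnames(ev$hess) <- list(colnames(pairs$X), colnames(pairs$X))
    return(ev)
  }
  stopifnot(inherits(pairs, "pair_set"))
  D <- pairs$differences
  p <- ncol(D)
  beta <- check_beta(beta, p)
  if (nrow(D) == 0L) {
    return(list(ll = 0, grad = numeric(p),
                hess = matrix(0, p, p), d_k = 0))
  }
  z <- pair_linpred(D, beta)
  ll <- -sum(log1pexp(-z))
  grad <- numeric(p); hess <- matrix(0, p, p)
  if (order >= 1L) {
    w <- plogis(-z)
    grad <- drop(crossprod(D, w))
    if (order >= 2L) hess <- -crossprod(D, D * (w * (1 - w)))
  }
  names(grad) <- colnames(D)
  list(ll = ll, grad = grad, hess = hess, d_k = pairs$d_k)
}

#' Pairwise conditional logistic log-likelihood
#'
#' For each discordant pair with covariate difference d the conditional
#' probability that the observed case is the case (given that exactly one of
#' the two is) is `plogis(beta' d)`, which is free of any site-level
#' intercept.  The site log-likelihood is the unnormalized sum
#' `sum_m -log(1 + exp(-beta' d_m))` over all its discordant pairs; an
#' empty pair set contributes 0 by convention.
#'
#' @param beta Coefficient vector (log odds-ratio scale, no intercept).
#' @param pairs A `pair_set` from [build_pairs()], or a [site_data()] object
#'   (evaluated by a streaming kernel without materializing the pairs).
#' @return Scalar log-likelihood, finite for `|beta' d|` up to 700.
#' @examples
#' s <- site_data("A", c(1, 1, 0, 0), cbind(x = c(2, 0, 1, -1)))
#' pairwise_loglik(0, s)        # -4 * log(2): four pairs at beta = 0
#' @seealso [pairwise_score()], [pairwise_hessian()]
#' @export
pairwise_loglik <- function(beta, pairs) pair_eval(beta, pairs, 0L)$ll

#' Gradient of the pairwise conditional logistic log-likelihood
#'
#' Analytic score `sum_m d_m * plogis(-beta' d_m)`.
#'
#' @inheritParams pairwise_loglik
#' @return Numeric vector of length p.
#' @export
pairwise_score <- function(beta, pairs) pair_eval(beta, pairs, 1L)$grad

#' Hessian of the pairwise conditional logistic log-likelihood
#'
#' Analytic Hessian `-sum_m d_m d_m' * w_m (1 - w_m)` with
#' `w_m = plogis(beta' d_m)`; symmetric and negative semidefinite for every
#' beta (the objective is concave).
#'
#' @inheritParams pairwise_loglik
#' @return p x p matrix.
#' @export
pairwise_hessian <- function(beta, pairs) pair_eval(beta, pairs, 2L)$hess
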