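# ---- RNG streams ----------------------------------------------------------
# A master seed spawns independent L'Ecuyer-CMRG streams per replicate and
# substreams per site, so changing K or the replicate count never correlates
# draws across units.

make_stream_seed <- function(seed) {
  old_kind <- RNGkind()
  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    restore_rng(old_seed)
  })
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  get(".Random.seed", globalenv())
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", globalenv()))
    rm(".Random.seed", envir = globalenv())
}

replicate_stream <- function(master, replicate) {
  s <- master
  for (r in seq_len(replicate)) s <- parallel::nextRNGStream(s)
  s
}

# ---- scenario configuration ----------------------------------------------

# prevalence ranges for the three canonical medians; a generic symmetric
# rule covers other medians
default_prevalence_range <- function(median, heterogeneity) {
  canonical <- list(
    moderate = list(`0.2` = c(0.15, 0.25), `0.05` = c(0.035, 0.065),
                    `0.005` = c(0.003, 0.007)),
    large = list(`0.2` = c(0.10, 0.30), `0.05` = c(0.02, 0.08),
                 `0.005` = c(0.001, 0.010)))
  key <- as.character(median)
  r <- canonical[[heterogeneity]][[key]]
  if (!is.null(r)) return(r)
  half <- switch(heterogeneity, moderate = 0.25, large = 0.5) * median
  c(max(median - half, median / 10), min(median + half, 1 - 1e-6))
}

#' Configuration of a synthetic multi-site scenario
#'
#' Describes one simulation condition: K sites whose sample sizes are drawn
#' uniformly from `n_range`, two (by default) covariates — a standard
#' normal continuous one and a Bernoulli(0.5) binary one — and site-level
#' outcome prevalences drawn uniformly from `prevalence_range`, realized
#' through site-specific intercepts solved to match each target prevalence.
#' The default ranges are symmetric about the median with a wider spread
#' under `heterogeneity = "large"`:
#' moderate = \[.15,.25\]/\[.035,.065\]/\[.003,.007\] and
#' large = \[.10,.30\]/\[.02,.08\]/\[.001,.010\] for medians 20%/5%/0.5%.
#'
#' @param K Number of sites.
#' @param n_range Integer range `c(min, max)` of per-site sample sizes
#'   (default 800–1200).
#' @param prevalence_median Median site prevalence (default 0.2).
#' @param heterogeneity `"moderate"` or `"large"` between-site spread.
#' @param prevalence_range Optional explicit `c(low, high)` overriding the
#'   defaults.
#' @param beta_true True log odds ratios, one per covariate (default
#'   `c(x1 = 1, x2 = 0.5)`).
#' @param covariates List describing each covariate:
#'   `list(type = "continuous")` (standard normal) or
#'   `list(type = "binary", prob = )`.
#' @param seed Master seed for the scenario.
#' @return A validated `scenario_config`.
#' @export
scenario_config <- function(K = 20L, n_range = c(800L, 1200L),
                            prevalence_median = 0.2,
                            heterogeneity = c("moderate", "large"),
                            prevalence_range = NULL,
                            beta_true = c(x1 = 1.0, x2 = 0.5),
                            covariates = list(
                              x1 = list(type = "continuous"),
                              x2 = list(type = "binary", prob = 0.5)),
                            seed = 1L) {
  heterogeneity <- match.arg(heterogeneity)
  if (is.null(prevalence_range))
    prevalence_range <- default_prevalence_range(prevalence_median,
                                                 heterogeneity)
  stopifnot(K >= 1, length(n_range) == 2, n_range[1] >= 1,
            n_range[1] <= n_range[2],
            length(prevalence_range) == 2,
            prevalence_range[1] > 0, prevalence_range[2] < 1,
            prevalence_range[1] <= prevalence_median,
            prevalence_median <= prevalence_range[2],
            length(beta_true) == length(covariates),
            all(is.finite(beta_true)))
  if (is.null(names(covariates)))
    names(covariates) <- paste0("x", seq_along(covariates))
  names(beta_true) <- names(covariates)
  structure(list(K = as.integer(K), n_range = as.integer(n_range),
                 prevalence_median = prevalence_median,
                 prevalence_range = prevalence_range,
                 heterogeneity = heterogeneity,
                 beta_true = beta_true, covariates = covariates,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# ---- intercept solving ----------------------------------------------------

# quadrature grid over the covariate distribution: Gauss-Hermite for each
# continuous covariate, exact enumeration for each binary covariate
covariate_grid <- function(beta, covariates, gh_nodes = 64L) {
  parts <- lapply(seq_along(covariates), function(j) {
    cv <- covariates[[j]]
    if (cv$type == "continuous") {
      gh <- pracma::gaussHermite(gh_nodes)
      list(lin = sqrt(2) * gh$x * beta[j], w = gh$w / sqrt(pi))
    } else if (cv$type == "binary") {
      pr <- cv$prob %||% 0.5
      list(lin = c(0, beta[j]), w = c(1 - pr, pr))
    } else stop("unknown covariate type '", cv$type, "'")
  })
  lin <- 0; w <- 1
  for (pt in parts) {
    lin <- rep(lin, times = length(pt$lin)) +
      rep(pt$lin, each = length(lin))
    w <- rep(w, times = length(pt$w)) * rep(pt$w, each = length(w))
  }
  list(lin = lin, w = w)
}

#' Solve the site intercept matching a target prevalence
#'
#' Finds alpha such that the marginal event probability
#' `E_x[plogis(alpha + beta' x)]` equals `target_prev`, with the
#' expectation computed by Gauss-Hermite quadrature over continuous
#' covariates and exact summation over binary ones.  The map from alpha to
#' prevalence is a strictly increasing bijection onto (0, 1), so the root
#' is unique.
#'
#' @param target_prev Target prevalence in (0, 1).
#' @param beta True coefficient vector.
#' @param covariates Covariate specification as in [scenario_config()].
#' @param tol Root-finding tolerance on alpha.
#' @return The intercept alpha (scalar).
#' @examples
#' solve_intercept(0.2, 0, list(list(type = "continuous"))) # qlogis(0.2)
#' @export
solve_intercept <- function(target_prev, beta,
                            covariates = list(x1 = list(type = "continuous"),
                                              x2 = list(type = "binary",
                                                        prob = 0.5)),
                            tol = 1e-12) {
  stopifnot(target_prev > 0, target_prev < 1)
  grid <- covariate_grid(as.numeric(beta), covariates)
  f <- function(alpha) sum(grid$w * plogis(alpha + grid$lin)) - target_prev
  lo <- qlogis(target_prev) - 30; hi <- qlogis(target_prev) + 30
  uniroot(f, c(lo, hi), tol = tol)$root
}

# ---- generation -----------------------------------------------------------

#' Draw site-level target prevalences
#'
#' K independent Uniform(low, high) draws on the scenario's prevalence
#' range (whose midpoint is the scenario median by construction of the
#' defaults).  Uses the current RNG state; [generate_multisite()] manages
#' streams so the vector is reproducible from the scenario seed.
#'
#' @param config A [scenario_config()].
#' @return Numeric vector of length K.
#' @export
draw_site_prevalences <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  runif(config$K, config$prevalence_range[1], config$prevalence_range[2])
}

draw_covariates <- function(n, covariates) {
  X <- matrix(NA_real_, n, length(covariates),
              dimnames = list(NULL, names(covariates)))
  for (j in seq_along(covariates)) {
    cv <- covariates[[j]]
    X[, j] <- switch(cv$type,
                     continuous = rnorm(n),
                     binary = rbinom(n, 1, cv$prob %||% 0.5),
                     stop("unknown covariate type '", cv$type, "'"))
  }
  X
}

#' Generate heterogeneous multi-site binary-outcome data
#'
#' For each site: draw `n_k ~ DiscreteUniform(n_range)`, covariates from
#' their specified distributions, solve the site intercept `alpha_k` so the
#' marginal event probability equals the site's target prevalence, and draw
#' `y ~ Bernoulli(plogis(alpha_k + beta' x))`.  Deterministic given
#' `config$seed` and `replicate`; distinct replicates and sites use
#' independent RNG (sub)streams.
#'
#' @param config A [scenario_config()].
#' @param replicate Replicate index (>= 1); each replicate is an
#'   independent stream of the master seed.
#' @return A `multisite_data` with elements `sites` (list of
#'   [site_data()]) and `truth` (`beta_true`, per-site `alpha`, target
#'   `prevalence`, realized `n_k`, and the config).  Truth exists only for
#'   synthetic data.
#' @export
generate_multisite <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "scenario_config"), replicate >= 1)
  master <- make_stream_seed(config$seed)
  rep_stream <- replicate_stream(master, replicate)
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old), add = TRUE)

  assign(".Random.seed", rep_stream, envir = globalenv())
  prev <- draw_site_prevalences(config)
  n_k <- sample(seq(config$n_range[1], config$n_range[2]), config$K,
                replace = TRUE)
  alpha <- vapply(prev, solve_intercept, numeric(1),
                  beta = config$beta_true, covariates = config$covariates)

  site_stream <- rep_stream
  sites <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    site_stream <- parallel::nextRNGSubStream(site_stream)
    assign(".Random.seed", site_stream, envir = globalenv())
    X <- draw_covariates(n_k[k], config$covariates)
    pr <- plogis(alpha[k] + drop(X %*% config$beta_true))
    y <- rbinom(n_k[k], 1, pr)
    sites[[k]] <- site_data(sprintf("site%03d", k), y, X)
  }
  structure(list(sites = sites,
                 truth = list(beta_true = config$beta_true, alpha = alpha,
                              prevalence = prev, n_k = n_k,
                              config = config, replicate = replicate)),
            class = "multisite_data")
}

#' @export
print.multisite_data <- function(x, ...) {
  n <- vapply(x$sites, function(s) length(s$y), numeric(1))
  cases <- vapply(x$sites, function(s) sum(s$y), numeric(1))
  cat(sprintf(paste0("<multisite_data: %d sites, %d subjects, ",
                     "%d cases (prevalence %.3g)>\n"),
              length(x$sites), sum(n), sum(cases), sum(cases) / sum(n)))
  invisible(x)
}
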