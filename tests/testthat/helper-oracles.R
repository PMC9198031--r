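# Independent brute-force oracles, deliberately naive: double loops over
# subjects, no shared code with the package internals.

naive_pair_differences <- function(y, X) {
  X <- as.matrix(X)
  out <- NULL
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (y[i] == 1 && y[j] == 0) out <- rbind(out, X[i, ] - X[j, ])
  }
  if (is.null(out)) matrix(numeric(0), 0, ncol(X)) else out
}

naive_loglik <- function(beta, y, X) {
  D <- naive_pair_differences(y, X)
  if (nrow(D) == 0) return(0)
  tot <- 0
  for (m in seq_len(nrow(D)))
    tot <- tot - log(1 + exp(-sum(beta * D[m, ])))
  tot
}

naive_score_fd <- function(beta, y, X, h = 1e-6) {
  vapply(seq_along(beta), function(l) {
    e <- replace(numeric(length(beta)), l, h)
    (naive_loglik(beta + e, y, X) - naive_loglik(beta - e, y, X)) / (2 * h)
  }, numeric(1))
}

hessian_fd <- function(beta, pairs, h = 1e-6) {
  p <- length(beta)
  H <- matrix(NA_real_, p, p)
  for (l in seq_len(p)) {
    e <- replace(numeric(p), l, h)
    H[, l] <- (pairwise_score(beta + e, pairs) -
                 pairwise_score(beta - e, pairs)) / (2 * h)
  }
  (H + t(H)) / 2
}

# grid-search maximizer of the summed pairwise log-likelihood, p = 1
grid_search_pooled <- function(sites, lo = -5, hi = 5, step = 1e-3) {
  grid <- seq(lo, hi, by = step)
  obj <- vapply(grid, function(b)
    sum(vapply(sites, function(s) naive_loglik(b, s$y, s$X), numeric(1))),
    numeric(1))
  grid[which.max(obj)]
}

# per-subject aggregated pair scores + sandwich pieces by double loop
naive_sandwich <- function(beta, sites) {
  p <- length(beta)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  for (s in sites) {
    U <- matrix(0, length(s$y), p)
    P <- matrix(0, p, p)
    for (i in seq_along(s$y)) for (j in seq_along(s$y)) {
      if (s$y[i] == 1 && s$y[j] == 0) {
        d <- s$X[i, ] - s$X[j, ]
        w <- plogis(-sum(beta * d))
        sc <- w * d
        U[i, ] <- U[i, ] + sc
        U[j, ] <- U[j, ] + sc
        P <- P + outer(sc, sc)
        A <- A + outer(d, d) * w * (1 - w)
      }
    }
    B <- B + crossprod(U) - P
  }
  solve(A) %*% B %*% solve(A)
}

# small deterministic site generator for property loops
random_site <- function(n, p = 2, prev = 0.4, id = "s") {
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rbinom(n, 1, prev)
  if (all(y == 1)) y[1] <- 0
  if (all(y == 0)) y[1] <- 1
  site_data(id, y, X)
}

quiet_dclr <- function(expr) {
  old <- options(dclr.quiet = TRUE)
  on.exit(options(old))
  expr
}
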