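# Newton maximizer with step-halving for smooth concave objectives.
#
# fn(beta, order) must return list(ll, grad, hess) (order 2) or list(ll)
# (order 0).  Convergence: gradient infinity-norm <= tol.  The candidate
# step is evaluated directly at order 2 so the common accept path costs one
# evaluation per iteration; near the optimum, objective changes fall below
# summation rounding for large pair counts, so a candidate is also accepted
# when the predicted improvement g's is within rounding of zero.  On
# curvature trouble (singular -H) the Hessian is jittered; if that fails
# the fit falls back to BFGS with the analytic gradient.
newton_maximize <- function(fn, start, tol = 1e-8, max_iter = 100L) {
  beta <- as.numeric(start)
  flags <- character(0)
  ev <- fn(beta, 2L)
  iter <- 0L
  converged <- FALSE
  repeat {
    if (!is.finite(ev$ll) || !all(is.finite(ev$grad))) {
      flags <- c(flags, "nonfinite_objective")
      break
    }
    if (max(abs(ev$grad)) <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    step <- newton_step(ev$hess, ev$grad)
    if (is.null(step)) {
      flags <- c(flags, "bfgs_fallback")
      bf <- bfgs_fallback(fn, beta)
      beta <- bf$beta; ev <- fn(beta, 2L)
      iter <- iter + bf$iter
      converged <- max(abs(ev$grad)) <= max(tol, 1e-6)
      break
    }
    rounding <- 1e-9 * (1 + abs(ev$ll))
    pred <- sum(ev$grad * step)          # >= 0 for concave objectives
    cand <- beta + step
    ev_c <- fn(cand, 2L)
    if (is.finite(ev_c$ll) &&
        (ev_c$ll >= ev$ll - rounding || pred <= 1e3 * rounding)) {
      beta <- cand; ev <- ev_c
    } else {
      # step halving on the objective alone
      t <- 0.5; accepted <- FALSE
      while (t >= 1e-12) {
        cand <- beta + t * step
        ll_t <- fn(cand, 0L)$ll
        if (is.finite(ll_t) && ll_t >= ev$ll - rounding) {
          accepted <- TRUE; break
        }
        t <- t / 2
      }
      flags <- unique(c(flags, "step_halved"))
      if (!accepted) { flags <- c(flags, "line_search_stall"); break }
      beta <- cand; ev <- fn(beta, 2L)
    }
    iter <- iter + 1L
  }
  list(beta = beta, ll = ev$ll, grad = ev$grad, hess = ev$hess,
       converged = converged, iter = iter,
       grad_norm = max(abs(ev$grad)), flags = flags)
}

# solve(-H, g) with escalating ridge jitter; NULL when hopeless
newton_step <- function(hess, grad) {
  A <- -hess
  scale <- mean(abs(diag(A)))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (jit in c(0, 1e-10, 1e-6, 1e-3)) {
    Aj <- A + diag(jit * scale, nrow(A))
    ch <- tryCatch(chol(Aj), error = function(e) NULL)
    if (!is.null(ch)) return(backsolve(ch, forwardsolve(t(ch), grad)))
  }
  NULL
}

bfgs_fallback <- function(fn, start) {
  res <- optim(start, fn = function(b) -fn(b, 0L)$ll,
               gr = function(b) -fn(b, 1L)$grad,
               method = "BFGS",
               control = list(maxit = 500L, reltol = 1e-14))
  list(beta = res$par, iter = as.integer(res$counts[["function"]]))
}
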