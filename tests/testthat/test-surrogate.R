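make_ms <- function(K = 3, n = 120, seed = 17, prev = 0.3) {
  set.seed(seed)
  lapply(seq_len(K), function(k) random_site(n, p = 2, prev = prev,
                                             id = paste0("s", k)))
}

test_that("surrogate corrections vanish for a single site", {
  sites <- make_ms(K = 1)
  anchor <- coef(fit_local(sites[[1]]))
  derivs <- lapply(sites, emit_derivatives, anchor = anchor)
  surr <- build_surrogate(anchor, derivs, sites[[1]])
  expect_equal(unname(surr$grad_correction), c(0, 0))
  expect_equal(unname(surr$hess_correction), matrix(0, 2, 2))
})

test_that("surrogate gradient at the anchor equals the pooled average gradient", {
  sites <- make_ms(K = 3)
  initials <- lapply(sites, emit_initial)
  anchor <- initial_average(initials)
  derivs <- lapply(sites, emit_derivatives, anchor = anchor)
  for (lead in c(1, 3)) {
    surr <- build_surrogate(anchor, derivs, sites[[lead]])
    g_surr <- surr$fn(anchor, 1L)$grad
    # recompute the average gradient directly from patient-level data
    g_pool <- Reduce(`+`, lapply(sites, function(s)
      pairwise_score(anchor, s)))
    d_tot <- sum(vapply(sites, function(s) build_pairs(s)$d_k, numeric(1)))
    expect_equal(unname(g_surr), unname(g_pool) / d_tot, tolerance = 1e-10)
  }
})

test_that("dCLR degenerates to pooled (K = 1) and to local (identical sites)", {
  sites <- make_ms(K = 1)
  fd <- fit_dclr(sites)
  fp <- fit_pooled(sites)
  expect_equal(coef(fd), coef(fp), tolerance = 1e-7)

  st <- make_ms(K = 1)[[1]]
  clones <- lapply(1:4, function(k) site_data(paste0("c", k), st$y, st$X))
  fd2 <- fit_dclr(clones)
  fl <- fit_local(st)
  expect_equal(unname(coef(fd2)), unname(coef(fl)), tolerance = 1e-7)
  expect_equal(fd2$diagnostics$communication_rounds, 2L)
})

test_that("dCLR tracks the pooled estimator on heterogeneous sites", {
  cfg <- scenario_config(K = 5, n_range = c(400L, 600L),
                         prevalence_median = 0.2, seed = 91L)
  diffs <- c()
  for (r in 1:3) {
    ms <- generate_multisite(cfg, replicate = r)
    fp <- fit_pooled(ms)
    fd <- fit_dclr(ms)
    diffs <- rbind(diffs, abs(coef(fd) - coef(fp)))
  }
  se <- sqrt(diag(sandwich_variance(fp, ms)))
  expect_true(all(colMeans(diffs) <= 0.2 * se))
})

test_that("lead selection modes work and inestimable sites are excluded", {
  sites <- make_ms(K = 3)
  empty <- site_data("empty", rep(0, 10),
                     cbind(x1 = rnorm(10), x2 = rnorm(10)))
  all4 <- c(sites, list(empty))
  fd <- fit_dclr(all4)
  expect_equal(fd$diagnostics$excluded_sites, "empty")
  expect_equal(length(fd$diagnostics$lead_sites), 3)

  f1 <- fit_dclr(all4, lead_selection = "max_pairs")
  expect_equal(length(f1$diagnostics$lead_sites), 1)
  f2 <- fit_dclr(all4, lead_selection = "s2")
  expect_equal(f2$diagnostics$lead_sites, "s2")
  expect_error(fit_dclr(all4, lead_selection = "empty"), "inestimable")

  # first-order surrogate also runs
  fo <- fit_dclr(sites, order = "first")
  expect_true(all(is.finite(coef(fo))))
})

test_that("payload validation rejects tampering and non-finite entries", {
  sites <- make_ms(K = 2)
  anchor <- c(0.1, -0.2)
  derivs <- lapply(sites, emit_derivatives, anchor = anchor)
  expect_silent(validate_round(derivs, expected_anchor = anchor))

  bad <- derivs
  bad[[2]]$anchor_fingerprint <- anchor_fingerprint(anchor + 1e-9)
  expect_error(validate_round(bad, expected_anchor = anchor),
               "s2.*fingerprint|fingerprint.*s2")

  nan <- derivs
  nan[[1]]$gradient[1] <- NaN
  expect_error(validate_round(nan, expected_anchor = anchor), "s1")

  asym <- derivs
  asym[[1]]$hessian[1, 2] <- asym[[1]]$hessian[1, 2] + 1e-6
  expect_error(validate_round(asym, expected_anchor = anchor),
               "not symmetric")
})
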