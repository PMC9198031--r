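test_that("fit_local finds the symmetric zero and flags separation", {
  sym <- site_data("A", c(1, 0, 0), cbind(x = c(0, -1, 1)))
  f <- fit_local(sym)
  expect_true(f$converged)
  expect_equal(unname(coef(f)), 0, tolerance = 1e-8)

  # a single discordant pair has a monotone likelihood
  sep <- site_data("B", c(1, 0), cbind(x = c(1, 0)))
  fs <- fit_local(sep)
  expect_true("separation_ridge_fallback" %in% fs$diagnostics$flags)
  expect_equal(fs$diagnostics$ridge, 1e-4)
  expect_true(all(is.finite(coef(fs))))

  none <- site_data("C", c(0, 0), cbind(x = c(1, 2)))
  expect_error(fit_local(none), "inestimable")
})

test_that("fit_local recovers the truth on simulated data", {
  cfg <- scenario_config(K = 1, n_range = c(1000L, 1000L),
                         prevalence_median = 0.2,
                         prevalence_range = c(0.2, 0.2), seed = 2024L)
  ms <- generate_multisite(cfg)
  f <- fit_local(ms$sites[[1]])
  expect_true(f$converged)
  # within 3 sandwich SEs of the truth (model-based SEs understate the
  # pair-sum information correlation)
  se <- sqrt(diag(sandwich_variance(f, ms$sites)))
  expect_true(all(abs(coef(f) - c(1.0, 0.5)) <= 3 * se))
})

test_that("fit_pooled degenerates correctly and matches a grid-search oracle", {
  set.seed(61)
  st <- random_site(12, p = 2)
  one <- fit_pooled(list(st))
  loc <- fit_local(st)
  expect_equal(coef(one), coef(loc), tolerance = 1e-8)

  # duplicated sites double the objective but keep the argmax
  twice <- fit_pooled(list(st, site_data("copy", st$y, st$X)))
  expect_equal(coef(twice), coef(one), tolerance = 1e-7)
  expect_equal(twice$objective, 2 * one$objective, tolerance = 1e-8)

  # tiny 2-site instance vs brute-force grid on [-5, 5] step 1e-3
  s1 <- site_data("g1", c(1, 0, 0, 1), cbind(x = c(0.5, -0.2, 1.1, 0.9)))
  s2 <- site_data("g2", c(0, 1, 1, 0), cbind(x = c(0.3, 0.8, -0.4, -1.0)))
  fit <- fit_pooled(list(s1, s2))
  grid <- grid_search_pooled(list(s1, s2))
  expect_lt(abs(unname(coef(fit)) - grid), 2e-3)
})

test_that("meta-analysis is the coordinate-wise inverse-variance average", {
  mk <- function(beta, var, id) {
    dclr:::new_fit_result("local", c(x = beta), matrix(var, 1, 1,
                          dimnames = list("x", "x")), TRUE, 1L,
                          diagnostics = list(site_id = id))
  }
  same <- fit_meta(list(mk(1.2, 0.5, "a"), mk(1.2, 0.5, "b")))
  expect_equal(unname(coef(same)), 1.2)

  eqw <- fit_meta(list(mk(1, 2, "a"), mk(3, 2, "b")))
  expect_equal(unname(coef(eqw)), 2)

  ivw <- fit_meta(list(mk(1, 1, "a"), mk(3, 3, "b")))
  expect_equal(unname(coef(ivw)), 1.5)          # (1/1 + 3/3) / (1 + 1/3)
  expect_equal(unname(vcov(ivw)[1, 1]), 1 / (1 + 1 / 3))

  # inestimable sites are excluded and recorded
  some <- fit_meta(list(mk(1, 1, "a"), NULL,
                        dclr:::new_fit_result("local", c(x = NaN), NULL,
                                              FALSE, 0L,
                                              diagnostics = list(site_id = "c"))))
  expect_equal(unname(coef(some)), 1)
  expect_equal(some$diagnostics$n_sites_used, 1)
  expect_error(fit_meta(list(NULL)), "no estimable")
})

test_that("initial_average applies the requested weighting scheme", {
  mk <- function(beta, n, id) structure(
    list(kind = "initial", site_id = id, beta_hat = c(x = beta),
         var_diag = c(x = 1), n_k = n, d_k = n, estimable = TRUE),
    class = "dclr_initial")
  two <- list(mk(0, 100, "a"), mk(4, 300, "b"))
  expect_equal(unname(initial_average(two)), 3)              # (0*100+4*300)/400
  expect_equal(unname(initial_average(two, "unweighted")), 2)
  three <- list(mk(1, 10, "a"), mk(2, 10, "b"), mk(3, 10, "c"))
  expect_equal(unname(initial_average(three, "unweighted")), 2)
  one <- list(mk(0.7, 50, "a"))
  expect_equal(unname(initial_average(one)), 0.7)
})
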