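test_that("solve_intercept matches logit closed forms and a Monte-Carlo oracle", {
  cont <- list(list(type = "continuous"))
  expect_equal(solve_intercept(0.2, 0, cont), qlogis(0.2), tolerance = 1e-8)
  expect_equal(solve_intercept(0.5, 0, cont), 0, tolerance = 1e-10)

  # monotone in the target prevalence
  a <- vapply(c(0.01, 0.05, 0.2, 0.5, 0.8), solve_intercept, numeric(1),
              beta = c(1, 0.5))
  expect_true(all(diff(a) > 0))

  # Monte-Carlo oracle at the default two-covariate design
  alpha <- solve_intercept(0.05, c(1.0, 0.5))
  set.seed(808)
  nmc <- 1e6
  x1 <- rnorm(nmc); x2 <- rbinom(nmc, 1, 0.5)
  pr <- plogis(alpha + 1.0 * x1 + 0.5 * x2)
  mc <- mean(pr)
  mc_se <- sd(pr) / sqrt(nmc)
  expect_lt(abs(mc - 0.05), 3 * mc_se + 1e-6)
})

test_that("site prevalences are drawn uniformly on the configured range", {
  cfg <- scenario_config(K = 200, prevalence_median = 0.2, seed = 5L)
  ms <- generate_multisite(cfg)
  prev <- ms$truth$prevalence
  expect_true(all(prev >= 0.15 & prev <= 0.25))
  expect_lt(abs(mean(prev) - 0.2), 3 * (0.1 / sqrt(12)) / sqrt(200))

  degen <- scenario_config(K = 5, prevalence_range = c(0.2, 0.2), seed = 5L)
  expect_equal(generate_multisite(degen)$truth$prevalence, rep(0.2, 5))
})

test_that("generation is bit-reproducible and respects the scenario", {
  cfg <- scenario_config(K = 4, n_range = c(50L, 80L), seed = 33L)
  a <- generate_multisite(cfg, replicate = 2)
  b <- generate_multisite(cfg, replicate = 2)
  expect_identical(a, b)
  c2 <- generate_multisite(cfg, replicate = 3)
  expect_false(identical(a$sites[[1]]$y, c2$sites[[1]]$y))

  expect_true(all(ms_n <- vapply(a$sites, function(s) length(s$y),
                                 numeric(1)) >= 50))
  expect_true(all(ms_n <= 80))
  expect_true(all(a$sites[[1]]$X[, "x2"] %in% c(0, 1)))

  # caller RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(generate_multisite(cfg))
  expect_identical(before, .Random.seed)
})

test_that("realized prevalences track their targets", {
  cfg <- scenario_config(K = 20, prevalence_median = 0.2, seed = 44L)
  emp <- c(); tgt <- c()
  for (r in 1:3) {
    ms <- generate_multisite(cfg, replicate = r)
    emp <- c(emp, vapply(ms$sites, function(s) mean(s$y), numeric(1)))
    tgt <- c(tgt, ms$truth$prevalence)
  }
  n_bar <- 1000
  se <- sqrt(mean(tgt * (1 - tgt)) / n_bar) / sqrt(length(emp))
  expect_lt(abs(mean(emp - tgt)), 3 * se)
})

test_that("offset logistic regression on generated data recovers the truth", {
  cfg <- scenario_config(K = 5, n_range = c(5000L, 5000L),
                         prevalence_median = 0.2, seed = 77L)
  ms <- generate_multisite(cfg)
  y <- unlist(lapply(ms$sites, `[[`, "y"))
  X <- do.call(rbind, lapply(ms$sites, `[[`, "X"))
  off <- rep(ms$truth$alpha, times = ms$truth$n_k)
  fit <- glm(y ~ 0 + X + offset(off), family = binomial())
  expect_true(all(abs(coef(fit) - c(1.0, 0.5)) <= 0.05))
})

test_that("the heterogeneity knob widens the prevalence spread", {
  mod <- scenario_config(K = 50, prevalence_median = 0.05,
                         heterogeneity = "moderate", seed = 10L)
  lar <- scenario_config(K = 50, prevalence_median = 0.05,
                         heterogeneity = "large", seed = 10L)
  v_mod <- var(generate_multisite(mod)$truth$prevalence)
  v_lar <- var(generate_multisite(lar)$truth$prevalence)
  expect_gt(v_lar, v_mod)
})

test_that("scenario_config validates its inputs", {
  expect_error(scenario_config(K = 0), "K")
  expect_error(scenario_config(prevalence_median = 0.3,
                               prevalence_range = c(0.4, 0.5)))
  expect_error(scenario_config(beta_true = c(1, 2, 3)))
  # canonical default ranges
  expect_equal(scenario_config(prevalence_median = 0.005)$prevalence_range,
               c(0.003, 0.007))
  expect_equal(scenario_config(prevalence_median = 0.005,
                               heterogeneity = "large")$prevalence_range,
               c(0.001, 0.010))
})
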