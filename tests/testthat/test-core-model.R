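test_that("build_pairs enumerates case-control differences", {
  s <- site_data("A", c(1, 1, 0, 0),
                 cbind(x = c(2, 0, 1, -1)))
  ps <- build_pairs(s)
  expect_equal(ps$d_k, 4)                      # 2 cases x 2 controls
  expect_equal(sort(drop(ps$differences)), sort(c(1, 3, -1, 1)))

  none <- site_data("B", c(0, 0, 0), cbind(x = c(1, 2, 3)))
  ps0 <- build_pairs(none)
  expect_equal(ps0$d_k, 0)
  expect_equal(nrow(ps0$differences), 0)

  single <- site_data("C", c(1, 0), cbind(x = c(2.0, 0.5)))
  expect_equal(unname(drop(build_pairs(single)$differences)), 1.5)
})

test_that("pairwise log-likelihood matches closed forms and the brute-force oracle", {
  s <- site_data("A", c(1, 1, 0, 0), cbind(x = c(2, 0, 1, -1)))
  # beta = 0: each of the D pairs contributes -log 2
  expect_equal(pairwise_loglik(0, s), -4 * log(2), tolerance = 1e-14)

  single <- site_data("C", c(1, 0), cbind(x1 = c(1, 0), x2 = c(3, 3)))
  expect_equal(pairwise_loglik(c(log(2), 0), single), log(2 / 3),
               tolerance = 1e-12)

  # brute-force double-loop oracle on several random instances
  set.seed(41)
  for (i in 1:5) {
    st <- random_site(8, p = 2, id = "r")
    beta <- rnorm(2)
    expect_equal(pairwise_loglik(beta, st), naive_loglik(beta, st$y, st$X),
                 tolerance = 1e-10)
    expect_equal(pairwise_loglik(beta, build_pairs(st)),
                 naive_loglik(beta, st$y, st$X), tolerance = 1e-10)
  }
})

test_that("site_data and pair_set likelihood paths agree", {
  set.seed(7)
  st <- random_site(15, p = 3)
  ps <- build_pairs(st)
  for (i in 1:3) {
    beta <- rnorm(3)
    expect_equal(pairwise_loglik(beta, st), pairwise_loglik(beta, ps),
                 tolerance = 1e-12)
    expect_equal(pairwise_score(beta, st), pairwise_score(beta, ps),
                 tolerance = 1e-12)
    expect_equal(pairwise_hessian(beta, st), pairwise_hessian(beta, ps),
                 tolerance = 1e-12)
  }
})

test_that("score has the beta = 0 closed form and matches finite differences", {
  set.seed(13)
  st <- random_site(10, p = 2)
  D <- build_pairs(st)$differences
  expect_equal(unname(pairwise_score(c(0, 0), st)),
               unname(colSums(D)) / 2,
               tolerance = 1e-12)

  single <- site_data("C", c(1, 0), cbind(x = c(1, 0)))
  expect_equal(unname(pairwise_score(log(2), single)), 1 / 3,
               tolerance = 1e-12)

  for (i in 1:5) {
    st <- random_site(8, p = 2)
    beta <- rnorm(2)
    fd <- naive_score_fd(beta, st$y, st$X)
    an <- unname(pairwise_score(beta, st))
    expect_equal(an, fd, tolerance = 1e-6)
  }
})

test_that("hessian matches closed form, finite differences, and is NSD", {
  single <- site_data("C", c(1, 0), cbind(x = c(2, 0)))
  expect_equal(pairwise_hessian(0, single), matrix(-1, 1, 1,
               dimnames = list("x", "x")), tolerance = 1e-14)

  empty <- site_data("D", c(0, 0), cbind(x1 = c(1, 2), x2 = c(0, 1)))
  expect_equal(unname(pairwise_hessian(c(0.3, -1), empty)),
               matrix(0, 2, 2))

  set.seed(29)
  for (i in 1:5) {
    st <- random_site(7, p = 2)
    beta <- rnorm(2)
    H <- pairwise_hessian(beta, st)
    expect_equal(unname(H), hessian_fd(beta, st), tolerance = 1e-5)
    expect_equal(H, t(H))
  }
})

test_that("concavity: hessian eigenvalues are never positive", {
  set.seed(101)
  for (i in 1:100) {
    st <- random_site(sample(4:12, 1), p = sample(1:3, 1))
    beta <- rnorm(ncol(st$X), sd = 2)
    ev <- eigen(pairwise_hessian(beta, st), symmetric = TRUE,
                only.values = TRUE)$values
    expect_lte(max(ev), 1e-10)
  }
})

test_that("intercept shifts leave the likelihood bit-identical", {
  set.seed(5)
  st <- random_site(12, p = 2)
  for (shift in c(0.5, -3, 100)) {
    X2 <- cbind(st$X, intercept = 1)
    st2 <- site_data(st$site_id, st$y, X2)
    beta <- c(0.7, -0.2)
    ll <- pairwise_loglik(beta, st)
    expect_identical(pairwise_loglik(c(beta, shift), st2), ll)
    expect_identical(pairwise_loglik(c(beta, shift), build_pairs(st2)),
                     pairwise_loglik(beta, build_pairs(st)))
  }
})

test_that("beta = 0 normalization holds to machine precision", {
  set.seed(77)
  for (i in 1:10) {
    st <- random_site(sample(3:20, 1), p = 2)
    dk <- build_pairs(st)$d_k
    expect_equal(pairwise_loglik(c(0, 0), st), -dk * log(2),
                 tolerance = 1e-13)
  }
})

test_that("no overflow for extreme linear predictors", {
  st <- site_data("A", c(1, 0), cbind(x = c(350, -350)))
  expect_true(is.finite(pairwise_loglik(1, st)))      # beta'd = 700
  expect_true(is.finite(pairwise_loglik(-1, st)))
  expect_true(all(is.finite(pairwise_score(1, st))))
  expect_true(all(is.finite(pairwise_hessian(1, st))))
  expect_equal(pairwise_loglik(-1, st), -700, tolerance = 1e-12)
})

test_that("matched 1:1 pairs reproduce the classical conditional likelihood", {
  skip_if_not_installed("survival")
  library(survival)
  set.seed(314)
  n_pairs <- 30
  sites <- lapply(seq_len(n_pairs), function(m) {
    X <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("x1", "x2")))
    site_data(paste0("pair", m), c(1, 0), X)
  })
  beta <- c(0.8, -0.3)
  ours <- sum(vapply(sites, function(s) pairwise_loglik(beta, s),
                     numeric(1)))
  # classical matched-pair CLR term: -log(1 + exp(-beta'(x1 - x0)))
  classical <- sum(vapply(sites, function(s) {
    d <- s$X[1, ] - s$X[2, ]
    -log(1 + exp(-sum(beta * d)))
  }, numeric(1)))
  expect_equal(ours, classical, tolerance = 1e-12)

  # and the pooled maximizer agrees with survival::clogit on pair strata
  df <- do.call(rbind, lapply(seq_along(sites), function(m)
    data.frame(y = sites[[m]]$y, sites[[m]]$X, stratum = m)))
  cl <- survival::clogit(y ~ x1 + x2 + strata(stratum), data = df)
  fit <- fit_pooled(sites)
  expect_equal(unname(coef(fit)), unname(coef(cl)), tolerance = 1e-6)
})
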