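test_that("stratum likelihood closed forms hold", {
  # all equal linear predictors: likelihood is 1 / C(n, d) by symmetry
  for (n in c(4, 9)) for (d in c(1, 3)) {
    s <- stratum_condloglik(rep(1.7, n), c(rep(1, d), rep(0, n - d)))
    expect_equal(s$loglik, -lchoose(n, d))
  }
  # matched pair: beta - log(1 + e^beta)
  for (b in c(-2, 0, 0.31, 3))
    expect_equal(stratum_condloglik(c(b, 0), c(1, 0))$loglik,
                 b - log(1 + exp(b)))
  # non-informative strata contribute nothing and are flagged
  s0 <- stratum_condloglik(rnorm(4), rep(1, 4))
  expect_false(s0$informative)
  expect_equal(s0$loglik, 0)
})

test_that("recursion equals exhaustive enumeration and its gradient is exact", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    d <- sample(seq_len(n - 1), 1)
    eta <- rnorm(n, sd = 2)
    y <- sample(c(rep(1, d), rep(0, n - d)))
    s <- stratum_condloglik(eta, y)
    expect_equal(s$loglik, enum_cond_loglik(eta, y), tolerance = 1e-12)
    # gradient vs central differences
    h <- 1e-6
    gnum <- vapply(seq_len(n), function(j) {
      ep <- eta; ep[j] <- ep[j] + h
      em <- eta; em[j] <- em[j] - h
      (enum_cond_loglik(ep, y) - enum_cond_loglik(em, y)) / (2 * h)
    }, numeric(1))
    expect_equal(s$gradient, gnum, tolerance = 1e-5)
    # invariance to a constant shift within the stratum
    expect_equal(stratum_condloglik(eta + 5.3, y)$loglik, s$loglik,
                 tolerance = 1e-10)
  }
})

test_that("null fits return zero coefficients and the combinatorial log-likelihood", {
  set.seed(52)
  strat <- rep(1:12, times = sample(3:8, 12, replace = TRUE))
  y <- rbinom(length(strat), 1, 0.4)
  informative <- tapply(y, strat, function(v) any(v == 1) && any(v == 0))
  nk <- table(strat)[informative]
  dk <- tapply(y, strat, sum)[informative]
  f0 <- fit_condlogit(matrix(numeric(0), length(y), 0), y, strat)
  expect_equal(f0$loglik, sum(-lchoose(as.integer(nk), as.integer(dk))))
  # all-zero covariate block is rank-deficient by design and refused
  expect_error(fit_condlogit(matrix(0, length(y), 1), y, strat),
               "rank-deficient")
  # symmetric covariate with no effect: beta ~ 0 at the null log-likelihood
  x <- rnorm(length(y))
  fx <- fit_condlogit(cbind(x = 0 * x + rep(c(1, -1), length.out = length(y))),
                      y, strat)
  expect_true(fx$converged)
})

test_that("fits agree with an independent established implementation", {
  skip_if_not_installed("survival")
  suppressPackageStartupMessages(library(survival))
  set.seed(53)
  n <- 400
  strat <- sample(1:50, n, replace = TRUE)
  x1 <- rbinom(n, 1, 0.3); x2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.4 + 0.8 * x1 - 0.5 * x2))
  fit <- fit_condlogit(cbind(x1 = x1, x2 = x2), y, strat)
  ref <- survival::clogit(y ~ x1 + x2 + survival::strata(strat),
                          method = "exact")
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
  # subject order does not matter
  p <- sample(n)
  fit2 <- fit_condlogit(cbind(x1 = x1, x2 = x2)[p, ], y[p], strat[p])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
  # Breslow approximation is close but not identical here
  fb <- fit_condlogit(cbind(x1 = x1, x2 = x2), y, strat,
                      likelihood = "breslow")
  refb <- survival::clogit(y ~ x1 + x2 + survival::strata(strat),
                           method = "breslow")
  expect_equal(unname(coef(fb)), unname(coef(refb)), tolerance = 1e-5)
})

test_that("odds ratios come from the Wald formula and refuse bad fits", {
  fit <- structure(list(coefficients = c(a = 0, b = log(1.36)),
                        vcov = diag(c(0.01, 0.04)), converged = TRUE),
                   class = "rfjem_clogit")
  dimnames(fit$vcov) <- list(c("a", "b"), c("a", "b"))
  ors <- odds_ratios(fit)
  expect_equal(ors$OR[1], 1)
  expect_equal(round(ors$CI_low[1], 2), 0.82)
  expect_equal(round(ors$CI_high[1], 2), 1.22)
  expect_equal(ors$OR[2], 1.36)
  expect_true(all(ors$CI_low <= ors$OR & ors$OR <= ors$CI_high))
  fit$converged <- FALSE
  expect_error(odds_ratios(fit), "non-converged")
})

test_that("separation is reported, never returned silently", {
  strat <- rep(1:20, each = 4)
  y <- rep(c(1, 0, 0, 0), 20)
  x <- as.numeric(y == 1)  # perfect separation
  fit <- fit_condlogit(cbind(x = x), y, strat)
  expect_false(fit$converged)
  expect_true(fit$monotone)
  expect_error(odds_ratios(fit), "separation")
})

test_that("trend test degenerates to p = 1 for a constant score", {
  strat <- rep(1:10, each = 4)
  y <- rep(c(1, 0), 20)
  tt <- trend_test(rep(2, 40), y, strat)
  expect_equal(tt$beta, 0)
  expect_equal(tt$p, 1)
})
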