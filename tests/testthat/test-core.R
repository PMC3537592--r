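test_that("log_ratio is the natural-log difference and antisymmetric", {
  expect_equal(log_ratio(2, 2), 0)
  expect_equal(log_ratio(exp(1), 1), 1)
  set.seed(5)
  for (i in 1:20) {
    a <- rlnorm(50)
    b <- rlnorm(50)
    expect_identical(log_ratio(a, b), -log_ratio(b, a))
  }
})

test_that("log_ratio rejects bad concentrations naming the samples", {
  a <- c(S1 = 1, S2 = -2, S3 = 3)
  b <- c(S1 = 1, S2 = 1, S3 = NA)
  err <- expect_error(log_ratio(a, b), class = "pgain_validation_error")
  expect_match(conditionMessage(err), "S2")
  expect_match(conditionMessage(err), "S3")
  expect_error(log_ratio(1:3, 1:2), class = "pgain_validation_error")
})

test_that("associate matches an independent normal-equations oracle", {
  set.seed(42)
  x <- rbinom(100, 2, 0.3)
  y <- 0.3 * x + rnorm(100)
  ref <- oracle_log10p(x, y)
  fit <- associate(x, y)
  expect_equal(fit$log10_p, ref$log10_p, tolerance = 1e-8)
  expect_equal(fit$beta, ref$beta, tolerance = 1e-10)
  expect_equal(fit$n_used, 100L)

  # with covariates, against the oracle and against summary.lm
  cv <- cbind(age = rnorm(100, 50, 8), bmi = rnorm(100, 26, 3))
  y2 <- 0.2 * x + 0.05 * cv[, "age"] + rnorm(100)
  ref2 <- oracle_log10p(x, y2, cv)
  fit2 <- associate(x, y2, cv)
  expect_equal(fit2$log10_p, ref2$log10_p, tolerance = 1e-8)
  sm <- summary(lm(y2 ~ cv + x))
  expect_equal(10^fit2$log10_p, sm$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-10)
})

test_that("associate p-values are uniform under the null", {
  set.seed(77)
  reps <- 10000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(40)
    p[i] <- 10^associate(x, rnorm(40))$log10_p
  }
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("associate handles degenerate and extreme inputs", {
  x <- rep(1:2, each = 10)
  expect_error(associate(rep(1, 20), rnorm(20)),
               class = "pgain_degenerate_error")
  expect_error(associate(x, rep(3, 20)), class = "pgain_degenerate_error")
  expect_error(associate(1:2, rnorm(2)), class = "pgain_degenerate_error")
  # perfect fit: the log-tail value is huge but never NaN
  fit <- associate(x, as.numeric(x))
  expect_false(is.nan(fit$log10_p))
  expect_lt(fit$log10_p, -15)
  expect_equal(fit$explained_variance, 1, tolerance = 1e-12)
  # near-perfect fit stays finite, far below linear-scale range
  set.seed(8)
  xx <- rnorm(2000)
  fit2 <- associate(xx, xx + rnorm(2000, sd = 0.01))
  expect_true(is.finite(fit2$log10_p))
  expect_lt(fit2$log10_p, -1000)
})

test_that("explained variance is the incremental R-squared of the trait", {
  set.seed(12)
  x <- rbinom(500, 2, 0.3)
  cv <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "c1"))
  y <- 0.4 * x + 0.8 * cv[, 1] + rnorm(500)
  fit <- associate(x, y, cv)
  r2_full <- summary(lm(y ~ cv + x))$r.squared
  r2_red <- summary(lm(y ~ cv))$r.squared
  expect_equal(fit$explained_variance, r2_full - r2_red, tolerance = 1e-10)
  expect_gte(fit$explained_variance, 0)
  expect_lte(fit$explained_variance, 1)
})

test_that("compute_pgain implements the log10 ratio of p-values", {
  expect_equal(compute_pgain(log10(1e-5), log10(1e-3), log10(1e-8)), 3)
  # quotient of a genome-wide single-metabolite p and a ratio p, as printed
  # for a desaturase locus: 2.3e-21 / 9.987e-66
  expect_equal(compute_pgain(log10(2.3e-21), log10(1e-20),
                             log10(9.987e-66)),
               44.3622927861, tolerance = 1e-6)
  # symmetric in the two single-metabolite arguments
  expect_identical(compute_pgain(-5, -3, -8), compute_pgain(-3, -5, -8))
  expect_error(compute_pgain(0.1, -3, -8), class = "pgain_domain_error")
})

test_that("pgain_linear saturates with an explicit flag", {
  res <- pgain_linear(c(2, 400))
  expect_equal(res$pgain[1], 100)
  expect_false(res$saturated[1])
  expect_true(res$saturated[2])
  expect_equal(res$pgain[2], .Machine$double.xmax)
  # log-space value reproduces the linear p-gain exactly when representable
  expect_identical(pgain_linear(log10(1e66))$pgain, 1e66)
})
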