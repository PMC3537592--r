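test_that("correlation settings are validated for positive semidefiniteness", {
  s <- correlation_setting(0.3, 0.2, 0.1)
  expect_s3_class(s, "correlation_setting")
  expect_equal(diag(s$matrix), c(M1 = 1, M2 = 1, ratio = 1))
  # exactly singular degenerate case is allowed
  expect_s3_class(correlation_setting(1, 0, 0), "correlation_setting")
  err <- expect_error(correlation_setting(0.9, -0.9, 0.9),
                      class = "pgain_domain_error")
  expect_match(conditionMessage(err), "eigenvalue")
  expect_error(correlation_setting(1.2, 0, 0),
               class = "pgain_domain_error")
})

test_that("inverse normal transform uses Blom scores on ranks", {
  # (r - 3/8)/(n + 1/4) at n = 3: 0.1923077, 0.5, 0.8076923
  got <- inverse_normal_transform(c(10, 2, 30))
  expect_equal(got, qnorm(c(0.5, 0.1923077, 0.8076923)), tolerance = 1e-6)
  expect_equal(got[1], 0)
  # monotone: strictly increasing input -> strictly increasing output
  v <- sort(rnorm(50))
  expect_true(all(diff(inverse_normal_transform(v)) > 0))
  # symmetry of the score set: tie-free input has mean exactly 0
  expect_equal(mean(inverse_normal_transform(rnorm(101))), 0,
               tolerance = 1e-10)
  # ties get average ranks, hence equal scores
  out <- inverse_normal_transform(c(1, 2, 2, 5))
  expect_identical(out[2], out[3])
  expect_error(inverse_normal_transform(rep(3, 10)),
               class = "pgain_degenerate_error")
  expect_error(inverse_normal_transform(2), class = "pgain_validation_error")
})

test_that("simulation is deterministic given a seed and needs one", {
  s <- correlation_setting(0.5, 0.3, 0.2)
  a <- simulate_pgain_null(s, n_samples = 50, n_reps = 200, seed = 99)
  b <- simulate_pgain_null(s, n_samples = 50, n_reps = 200, seed = 99)
  expect_identical(a$log10_pgains, b$log10_pgains)
  c <- simulate_pgain_null(s, n_samples = 50, n_reps = 200, seed = 100)
  expect_false(identical(a$log10_pgains, c$log10_pgains))
  expect_error(simulate_pgain_null(s, n_reps = 10),
               class = "pgain_validation_error")
})

test_that("the vectorised batch regression equals associate()", {
  s <- correlation_setting(0.4, 0.3, 0.1)
  n <- 60
  sim <- simulate_pgain_null(s, n_samples = n, n_reps = 1, seed = 123)
  # replay the identical RNG stream and route it through the scalar API
  L <- pgain:::copula_factor(s)
  set.seed(123)
  Z <- matrix(rnorm(3 * n), ncol = 3) %*% t(L)
  X <- rnorm(n)
  lp <- vapply(1:3, function(j) {
    associate(X, inverse_normal_transform(Z[, j]))$log10_p
  }, numeric(1))
  expect_equal(sim$log10_pgains, min(lp[1], lp[2]) - lp[3],
               tolerance = 1e-12)
})

test_that("degenerate setting (1,0,0) reproduces the analytic null", {
  sim <- simulate_pgain_null(correlation_setting(1, 0, 0),
                             n_samples = 500, n_reps = 20000, seed = 21)
  g <- 10^sim$log10_pgains
  ks <- suppressWarnings(ks.test(g, function(z) pgain_cdf(z)))
  expect_lt(unname(ks$statistic), 0.02)
  q <- empirical_quantiles(sim, c(0.5, 0.95))
  expect_equal(q$quantile_log10[1], 0, tolerance = 0.05)  # median p-gain 1
  expect_equal(q$quantile_linear[2], 10, tolerance = 0.15)
})

test_that("empirical quantiles are monotone and stable across halves", {
  sim <- simulate_pgain_null(correlation_setting(0.3, 0.2, 0.1),
                             n_samples = 100, n_reps = 20000, seed = 31)
  probs <- c(0.1, 0.5, 0.9, 0.95, 0.99)
  q <- empirical_quantiles(sim, probs)
  expect_true(all(diff(q$quantile_log10) >= 0))
  expect_equal(q$quantile_linear, 10^q$quantile_log10)
  h1 <- sim$log10_pgains[1:10000]
  h2 <- sim$log10_pgains[10001:20000]
  se1 <- bootstrap_quantile_se(h1, 0.95, seed = 1)
  se2 <- bootstrap_quantile_se(h2, 0.95, seed = 2)
  d <- abs(quantile(h1, 0.95, names = FALSE) -
             quantile(h2, 0.95, names = FALSE))
  expect_lt(d, 2 * sqrt(se1^2 + se2^2) + 1e-12)
  expect_error(empirical_quantiles(sim, numeric(0)),
               class = "pgain_validation_error")
})

test_that("simulated critical values demand adequate resolution", {
  err <- expect_error(
    simulated_critical_value(correlation_setting(0, 0, 0), alpha = 0.05,
                             B = 1e6, n_reps = 1e4, seed = 1),
    class = "pgain_validation_error")
  expect_match(conditionMessage(err), "n_reps >=")
  cv <- simulated_critical_value(correlation_setting(0.3, 0.2, 0.1),
                                 alpha = 0.05, B = 1, n_samples = 100,
                                 n_reps = 5000, seed = 6)
  expect_lt(as.numeric(cv), 12)
  expect_equal(attr(cv, "log10"), log10(as.numeric(cv)))
})
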