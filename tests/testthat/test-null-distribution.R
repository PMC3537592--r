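test_that("density and CDF follow the split ratio-of-uniforms form", {
  expect_equal(pgain_density(0.5), 0.5)
  expect_equal(pgain_density(2), 0.125)
  expect_equal(pgain_density(1), 0.5)  # continuous at the branch point
  expect_equal(pgain_density(1 - 1e-12), pgain_density(1 + 1e-12),
               tolerance = 1e-9)

  expect_equal(pgain_cdf(0.5), 0.25)
  expect_equal(pgain_cdf(1), 0.5)   # the null median p-gain is 1
  expect_equal(pgain_cdf(10), 0.95)

  expect_error(pgain_density(0), class = "pgain_domain_error")
  expect_error(pgain_cdf(-1), class = "pgain_domain_error")
})

test_that("quantile inverts the CDF on both branches", {
  expect_equal(pgain_quantile(0.95), 10)
  expect_equal(pgain_quantile(0.5), 1)
  expect_equal(pgain_quantile(0.25), 0.5)
  for (g in c(0.01, 0.5, 1, 10, 1e6)) {
    expect_equal(pgain_quantile(pgain_cdf(g)), g, tolerance = 1e-10)
  }
  expect_error(pgain_quantile(0), class = "pgain_domain_error")
  expect_error(pgain_quantile(1), class = "pgain_domain_error")
})

test_that("numerical integration of the density reproduces the CDF", {
  for (G in c(0.3, 1, 7, 100, 1e6)) {
    pieces <- if (G <= 1) {
      stats::integrate(pgain_density, 1e-12, G, rel.tol = 1e-12)$value
    } else {
      stats::integrate(pgain_density, 1e-12, 1, rel.tol = 1e-12)$value +
        stats::integrate(pgain_density, 1, G, rel.tol = 1e-12)$value
    }
    expect_equal(pieces, pgain_cdf(G), tolerance = 1e-8)
  }
  # density integrates to 1 over the whole support
  total <- stats::integrate(pgain_density, 1e-12, 1)$value +
    stats::integrate(function(g) pgain_density(g), 1, Inf)$value
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("tail probability is 1/(2g) and matches Bonferroni algebra", {
  expect_equal(pgain_tail_prob(10), 0.05)
  expect_equal(pgain_tail_prob(1), 0.5)
  # an observed p-gain of 10*B has tail probability alpha/B at alpha=0.05
  expect_equal(pgain_tail_prob(10 * 20), 0.05 / 20)
  expect_error(pgain_tail_prob(0.5), class = "pgain_domain_error")
})

test_that("critical value is B/(2 alpha) with the derivation's guard", {
  expect_identical(pgain_critical_value(0.05, 1), 10)
  for (B in c(1, 10, 100, 258)) {
    expect_equal(pgain_critical_value(0.05, B), 10 * B)
  }
  expect_equal(pgain_critical_value(0.05, 1e12, log10 = TRUE),
               log10(1e12) + 1)
  expect_error(pgain_critical_value(0.6, 1), class = "pgain_domain_error")
  expect_error(pgain_critical_value(0.05, 0), class = "pgain_domain_error")
  expect_error(pgain_critical_value(0.05, 2.5), class = "pgain_domain_error")
})

test_that("ratio of two independent uniforms matches the analytic null", {
  set.seed(101)
  n <- 1e5
  g <- runif(n) / runif(n)
  ks <- suppressWarnings(ks.test(g, function(z) pgain_cdf(z)))
  expect_lt(unname(ks$statistic), 0.005)
  expect_equal(mean(g > 10), 0.05, tolerance = 0.05)
})
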