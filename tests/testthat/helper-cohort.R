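# small cohorts used across test files

planted_cohort <- function(n = 500, seed = 1, beta = 0.25, n_null = 0L) {
  generate_cohort(generator_spec(n = n, maf = 0.3, beta1 = beta,
                                 beta2 = -beta, shared_sd = 1,
                                 noise_sd1 = 0.5, noise_sd2 = 0.5,
                                 n_null = n_null, seed = seed))
}

null_cohort <- function(n = 500, seed = 1, shared_sd = 0, n_null = 0L) {
  generate_cohort(generator_spec(n = n, maf = 0.3, shared_sd = shared_sd,
                                 noise_sd1 = 0.5, noise_sd2 = 0.5,
                                 n_null = n_null, seed = seed))
}

# independent textbook OLS: explicit normal equations + t tail
oracle_log10p <- function(x, y, covariates = NULL) {
  X <- cbind(1, covariates, x)
  xtx_inv <- solve(t(X) %*% X)
  beta_hat <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta_hat
  df <- length(y) - ncol(X)
  se <- sqrt(sum(res^2) / df * xtx_inv[ncol(X), ncol(X)])
  tstat <- beta_hat[ncol(X)] / se
  list(beta = beta_hat[ncol(X)],
       log10_p = (log(2) + pt(abs(tstat), df, lower.tail = FALSE,
                              log.p = TRUE)) / log(10))
}
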