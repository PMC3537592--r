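#' Correlation setting for p-gain simulation
#'
#' The exact distribution of the p-gain for a specific metabolite ratio is
#' driven by three pairwise correlations: between the two metabolites, and
#' between each metabolite and the ratio. They define the 3x3 correlation
#' matrix of the Gaussian copula used by [simulate_pgain_null()]. The
#' matrix must be positive semidefinite; eigenvalues down to -1e-8 are
#' tolerated (and clipped at zero), so exactly singular settings such as
#' `cor_m1_m2 = 1` — the degenerate case that reproduces the analytic
#' conservative null — are valid.
#'
#' @param cor_m1_m2 correlation between the two metabolites, in \[-1, 1\].
#' @param cor_m1_ratio,cor_m2_ratio correlation of each metabolite with the
#'   ratio, in \[-1, 1\].
#' @return An object of class `correlation_setting` holding the three
#'   correlations and the implied matrix.
#' @examples
#' correlation_setting(0.3, 0.2, 0.1)
#' correlation_setting(1, 0, 0)  # degenerate conservative case
#' @export
correlation_setting <- function(cor_m1_m2, cor_m1_ratio, cor_m2_ratio) {
  r <- c(cor_m1_m2, cor_m1_ratio, cor_m2_ratio)
  if (!is.numeric(r) || length(r) != 3L || any(!is.finite(r)) ||
      any(abs(r) > 1)) {
    pgain_domain_error("correlations must be three values in [-1, 1]")
  }
  R <- matrix(c(1, cor_m1_m2, cor_m1_ratio,
                cor_m1_m2, 1, cor_m2_ratio,
                cor_m1_ratio, cor_m2_ratio, 1), 3L, 3L,
              dimnames = list(c("M1", "M2", "ratio"),
                              c("M1", "M2", "ratio")))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    pgain_domain_error(paste0(
      "correlation matrix is not positive semidefinite ",
      "(minimum eigenvalue ", format(min(ev), digits = 6), ")"))
  }
  structure(list(cor_m1_m2 = cor_m1_m2, cor_m1_ratio = cor_m1_ratio,
                 cor_m2_ratio = cor_m2_ratio, matrix = R),
            class = "correlation_setting")
}

#' @export
print.correlation_setting <- function(x, ...) {
  cat("correlation_setting: cor(M1,M2) = ", x$cor_m1_m2,
      ", cor(M1,ratio) = ", x$cor_m1_ratio,
      ", cor(M2,ratio) = ", x$cor_m2_ratio, "\n", sep = "")
  invisible(x)
}

# factor L with L %*% t(L) equal to the (PSD-repaired) correlation matrix;
# eigenvalues clipped at 0, matrix rescaled to unit diagonal
copula_factor <- function(setting) {
  e <- eigen(setting$matrix, symmetric = TRUE)
  d <- pmax(e$values, 0)
  R <- e$vectors %*% (d * t(e$vectors))
  s <- 1 / sqrt(diag(R))
  R <- R * tcrossprod(s)
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)))
}

#' Rank-based inverse normal transformation
#'
#' Maps a variable to standard-normal quantiles through its ranks, using
#' Blom offsets: value of rank r among n becomes
#' `qnorm((r - 3/8) / (n + 1/4))`. Ties receive average ranks. The
#' transformation is monotone and makes the marginal distribution normal,
#' as linear regression assumes; it is applied to each copula margin before
#' the regressions that generate correlated p-values.
#'
#' @param v numeric vector, length >= 2, not all values identical.
#' @return numeric vector of normal scores, same length as `v`.
#' @examples
#' inverse_normal_transform(c(3.2, 1.1, 7.8))
#' @export
inverse_normal_transform <- function(v) {
  if (!is.numeric(v) || length(v) < 2L || any(!is.finite(v))) {
    pgain_validation_error(
      "input must be a finite numeric vector of length >= 2")
  }
  if (max(v) == min(v)) {
    pgain_degenerate_error("cannot normal-transform a constant vector")
  }
  r <- rank(v, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
}

#' Simulate the null distribution of the p-gain under correlation
#'
#' Monte Carlo estimation of the p-gain distribution for a given
#' correlation structure among M1, M2 and their ratio. Per replicate:
#' `n_samples` triples are drawn from a Gaussian copula with the setting's
#' correlation matrix (uniform margins), each margin is inverse-normal
#' transformed, an independent standard-normal predictor X is drawn, each
#' of the three traits is regressed on X, and the p-gain is formed from the
#' three p-values. The three traits are free margins tied only by the
#' correlation structure; the arithmetic identity ratio = M1/M2 is
#' deliberately not imposed.
#'
#' The regressions are evaluated in vectorised batches via the correlation
#' form of the simple-OLS t statistic; the result is numerically identical
#' to [associate()] without covariates.
#'
#' @param setting a [correlation_setting()].
#' @param n_samples per-replicate cohort size (>= 10).
#' @param n_reps number of replicates.
#' @param seed integer RNG seed; results are bit-for-bit reproducible.
#' @param batch_size replicates simulated per vectorised block (memory /
#'   speed trade-off only; does not change results for a fixed seed and
#'   batch size).
#' @return An object of class `pgain_simulation`: list with
#'   `log10_pgains` (length `n_reps`), `setting`, `n_samples`, `n_reps`,
#'   `seed`.
#' @examples
#' sim <- simulate_pgain_null(correlation_setting(1, 0, 0),
#'                            n_samples = 100, n_reps = 500, seed = 1)
#' stats::quantile(sim$log10_pgains, 0.95)  # near log10(10) = 1
#' @export
simulate_pgain_null <- function(setting, n_samples = 1000L,
                                n_reps = 100000L, seed,
                                batch_size = 1000L) {
  if (!inherits(setting, "correlation_setting")) {
    pgain_validation_error("setting must be a correlation_setting")
  }
  if (n_samples < 10L) pgain_validation_error("n_samples must be >= 10")
  if (n_reps < 1L) pgain_validation_error("n_reps must be >= 1")
  if (missing(seed)) pgain_validation_error("seed is required")

  L <- copula_factor(setting)
  n <- as.integer(n_samples)
  # Blom normal scores are a fixed set per n: transforming a tie-free
  # margin is a permutation of these, indexed by the ranks
  blom <- stats::qnorm((seq_len(n) - 3 / 8) / (n + 1 / 4))
  blom_ss <- sum(blom^2)  # scores sum to zero by symmetry
  df <- n - 2L

  set.seed(as.integer(seed))
  out <- numeric(n_reps)
  done <- 0L
  while (done < n_reps) {
    nb <- min(as.integer(batch_size), n_reps - done)
    N <- n * nb
    Z <- matrix(stats::rnorm(3L * N), ncol = 3L) %*% t(L)
    X <- matrix(stats::rnorm(N), n, nb)
    Xc <- sweep(X, 2L, colMeans(X))
    xss <- colSums(Xc^2)
    lp <- matrix(0, nb, 3L)
    for (j in 1:3) {
      Yj <- matrix(Z[, j], n, nb)
      # ranks are tie-free a.s.; map onto the fixed Blom scores
      Yj <- apply(Yj, 2L, function(col) blom[rank(col)])
      rho <- colSums(Xc * Yj) / sqrt(xss * blom_ss)
      tstat <- abs(rho) * sqrt(df / (1 - rho^2))
      lp[, j] <- log10_p_from_t(tstat, df)
    }
    out[done + seq_len(nb)] <- pmin(lp[, 1L], lp[, 2L]) - lp[, 3L]
    done <- done + nb
  }
  structure(list(log10_pgains = out, setting = setting,
                 n_samples = n, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "pgain_simulation")
}

#' @export
print.pgain_simulation <- function(x, ...) {
  cat("pgain_simulation: ", x$n_reps, " replicates of n = ", x$n_samples,
      " (seed ", x$seed, ")\n", sep = "")
  print(x$setting)
  q <- stats::quantile(x$log10_pgains, c(0.5, 0.95, 0.99), names = FALSE)
  cat("log10 p-gain quantiles: 50% = ", format(q[1], digits = 4),
      ", 95% = ", format(q[2], digits = 4),
      ", 99% = ", format(q[3], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Empirical quantiles of a simulated p-gain distribution
#'
#' Linear interpolation of order statistics (type-7 continuous quantiles)
#' on the log10 scale, reported on both scales.
#'
#' @param sim a `pgain_simulation` from [simulate_pgain_null()] with at
#'   least 100 replicates.
#' @param probs probabilities in (0, 1), non-empty.
#' @return data frame with columns `prob`, `quantile_log10`,
#'   `quantile_linear`.
#' @export
empirical_quantiles <- function(sim, probs) {
  if (!inherits(sim, "pgain_simulation")) {
    pgain_validation_error("sim must be a pgain_simulation")
  }
  if (sim$n_reps < 100L) {
    pgain_validation_error("at least 100 replicates are required")
  }
  if (length(probs) == 0L || !is.numeric(probs) || any(probs <= 0) ||
      any(probs >= 1)) {
    pgain_validation_error("probs must be a non-empty vector within (0, 1)")
  }
  ql <- stats::quantile(sim$log10_pgains, probs, type = 7, names = FALSE)
  data.frame(prob = probs, quantile_log10 = ql, quantile_linear = 10^ql)
}

#' Simulated critical p-gain for a correlation setting
#'
#' The empirical `1 - alpha/B` quantile of the simulated p-gain: the exact
#' (Monte Carlo) critical value for a specific correlation setting, always
#' at or below the analytic conservative value `B/(2 alpha)`.
#'
#' @inheritParams simulate_pgain_null
#' @param alpha family-wise significance level.
#' @param B number of tested ratio hypotheses (Bonferroni).
#' @param sim optionally, a precomputed `pgain_simulation` for `setting`;
#'   when supplied, `n_samples`, `n_reps` and `seed` are taken from it.
#' @return The critical p-gain on the linear scale, with the log10 value in
#'   `attr(, "log10")`.
#' @examples
#' simulated_critical_value(correlation_setting(0.3, 0.2, 0.1),
#'                          alpha = 0.05, B = 1,
#'                          n_samples = 100, n_reps = 2000, seed = 7)
#' @export
simulated_critical_value <- function(setting, alpha, B = 1,
                                     n_samples = 1000L, n_reps = 100000L,
                                     seed, sim = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1 || alpha / B >= 1) {
    pgain_domain_error("1 - alpha/B must lie in (0, 1)")
  }
  if (!is.null(sim)) n_reps <- sim$n_reps
  expected_exceed <- n_reps * alpha / B
  if (expected_exceed < 10) {
    pgain_validation_error(paste0(
      "quantile 1 - alpha/B = ", 1 - alpha / B, " cannot be resolved with ",
      n_reps, " replicates (expected exceedances ",
      format(expected_exceed, digits = 3),
      " < 10); use n_reps >= ", ceiling(10 * B / alpha)))
  }
  if (is.null(sim)) {
    sim <- simulate_pgain_null(setting, n_samples = n_samples,
                               n_reps = n_reps, seed = seed)
  }
  q <- empirical_quantiles(sim, 1 - alpha / B)
  structure(q$quantile_linear, log10 = q$quantile_log10)
}

#' Bootstrap standard error of an empirical quantile
#'
#' Resamples a Monte Carlo sample with replacement and returns the
#' standard deviation of the quantile across bootstrap replicates. Used to
#' judge whether two simulated quantiles differ beyond Monte Carlo noise.
#'
#' @param x numeric sample.
#' @param prob single probability in (0, 1).
#' @param n_boot number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @return standard error (single number).
#' @export
bootstrap_quantile_se <- function(x, prob, n_boot = 200L, seed = 1L) {
  if (length(prob) != 1L || prob <= 0 || prob >= 1) {
    pgain_domain_error("prob must be a single value in (0, 1)")
  }
  set.seed(as.integer(seed))
  n <- length(x)
  qs <- vapply(seq_len(n_boot), function(i) {
    stats::quantile(x[sample.int(n, n, replace = TRUE)], prob,
                    type = 7, names = FALSE)
  }, numeric(1))
  stats::sd(qs)
}
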