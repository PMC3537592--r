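#' Analytic null distribution of the conservative p-gain
#'
#' Under the conservative ("universal") definition of the p-gain, the
#' numerator and denominator p-values are independent Uniform(0,1)
#' variables, so the p-gain is distributed as the ratio of two independent
#' uniforms. The convolution formula for density ratios yields a split
#' density: constant 1/2 below 1 and 1/(2 g^2) above 1. These functions give
#' the density, distribution function, quantile function and upper-tail
#' probability of that null in closed form.
#'
#' The null is *conservative*: for any actual correlation among the two
#' metabolites and their ratio, the distribution of the observed p-gain is
#' stochastically dominated by this one, so critical values read from it are
#' valid (if cautious) for every correlation setting. See
#' [simulate_pgain_null()] for the exact distribution of a specific setting.
#'
#' @param g p-gain value(s), linear scale; must be strictly positive
#'   (`pgain_tail_prob()` additionally requires `g >= 1`).
#' @param q probability value(s) in (0, 1).
#' @return `pgain_density()` the density f(g); `pgain_cdf()` the
#'   distribution function F(g); `pgain_quantile()` the quantile function
#'   (inverse of F); `pgain_tail_prob()` the exceedance probability
#'   P(p-gain >= g) = 1/(2 g), i.e. the p-value attached to an observed
#'   conservative p-gain. All are vectorised.
#'
#' @examples
#' pgain_density(c(0.5, 1, 2))   # 0.5, 0.5, 0.125
#' pgain_cdf(10)                 # 0.95
#' pgain_quantile(0.95)          # 10
#' pgain_tail_prob(10)           # 0.05
#' @seealso [pgain_critical_value()] for Bonferroni-corrected thresholds.
#' @export
pgain_density <- function(g) {
  check_positive_pgain(g)
  ifelse(g < 1, 0.5, 1 / (2 * g^2))
}

#' @rdname pgain_density
#' @export
pgain_cdf <- function(g) {
  check_positive_pgain(g)
  ifelse(g < 1, g / 2, 1 - 1 / (2 * g))
}

#' @rdname pgain_density
#' @export
pgain_quantile <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    pgain_domain_error("quantile probabilities must lie strictly in (0, 1)")
  }
  ifelse(q < 0.5, 2 * q, 1 / (2 * (1 - q)))
}

#' @rdname pgain_density
#' @export
pgain_tail_prob <- function(g) {
  if (!is.numeric(g) || any(!is.finite(g)) || any(g < 1)) {
    pgain_domain_error(
      "tail probability is defined for p-gain >= 1 (the upper branch)")
  }
  1 / (2 * g)
}

#' Bonferroni-corrected critical value of the p-gain
#'
#' Inverting the null distribution function at 1 - alpha/B gives the
#' critical p-gain B/(2 alpha) for B tested ratio hypotheses at family-wise
#' level alpha. At alpha = 0.05 and a single test this is the classic
#' threshold of 10; with Bonferroni correction the uncorrected threshold of
#' 10 is simply multiplied by the number of tested ratios B. The inversion
#' uses the upper branch of the distribution function and is therefore only
#' valid while alpha/B <= 0.5.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param B number of tested ratio hypotheses (each unordered metabolite
#'   pair counted once), a positive integer. May exceed integer range; B up
#'   to 1e12 and beyond is handled exactly on the log10 scale.
#' @param log10 if `TRUE`, return log10 of the critical value (computed as
#'   `log10(B) - log10(2 * alpha)` so very large B never overflows).
#' @return The critical p-gain B/(2 alpha), linear or log10 scale.
#' @examples
#' pgain_critical_value(0.05, 1)            # 10
#' pgain_critical_value(0.05, 258)          # 2580
#' pgain_critical_value(0.05, 1e12, log10 = TRUE)
#' @export
pgain_critical_value <- function(alpha, B = 1, log10 = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1) {
    pgain_domain_error("alpha must be a single value in (0, 1)")
  }
  if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 1 ||
      B != floor(B)) {
    pgain_domain_error("B must be a single integer >= 1")
  }
  if (alpha / B > 0.5) {
    pgain_domain_error(paste0(
      "critical value requires alpha/B <= 0.5 (the inversion uses the ",
      "upper branch of the null CDF); got alpha/B = ", alpha / B))
  }
  if (log10) log10(B) - log10(2 * alpha) else B / (2 * alpha)
}

check_positive_pgain <- function(g) {
  if (!is.numeric(g) || any(!is.finite(g)) || any(g <= 0)) {
    pgain_domain_error("p-gain values must be finite and strictly positive")
  }
  invisible(g)
}
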