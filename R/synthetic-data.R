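#' Specification of a synthetic cohort
#'
#' Defines a desk-scale cohort with known ground truth for testing every
#' stage of a ratio scan. The model: a biallelic SNP genotype
#' `G ~ Binomial(2, maf)` (Hardy-Weinberg proportions) acts additively on
#' the log concentrations of two metabolites that also share a latent
#' log-normal component,
#' `log M1 = beta1 G + u + e1`, `log M2 = beta2 G + u + e2` with
#' `u ~ N(0, shared_sd^2)` and `e_i ~ N(0, noise_sd_i^2)`. Concentrations
#' are emitted on the linear (exponentiated) scale so the scan's log
#' handling is exercised; the trait is the genotype dosage.
#'
#' With opposite-sign effects (`beta1 = -beta2`, the default alternative)
#' the pair mimics the substrate and product of an enzymatic reaction: the
#' shared component `u` cancels in the ratio, so the ratio association is
#' far stronger than either single-metabolite association — the internal
#' normalisation that motivates ratio testing and a large p-gain.
#'
#' @param n sample count.
#' @param maf minor-allele frequency in (0, 0.5].
#' @param beta1,beta2 additive genotype effects on log M1 and log M2 (log
#'   concentration units per allele). Defaults of 0 give a null cohort.
#' @param shared_sd SD of the latent component common to both
#'   log-metabolites (controls their correlation).
#' @param noise_sd1,noise_sd2 residual SDs on the log scale; must be > 0.
#' @param n_null number of additional independent null metabolites
#'   (`log ~ N(0, 1)`), named `N1, N2, ...`, to pad a scan.
#' @param seed integer RNG seed.
#' @return An object of class `generator_spec`.
#' @examples
#' generator_spec(n = 1000, beta1 = 0.25, beta2 = -0.25, seed = 1)
#' @export
generator_spec <- function(n, maf = 0.3, beta1 = 0, beta2 = 0,
                           shared_sd = 1, noise_sd1 = 0.5,
                           noise_sd2 = 0.5, n_null = 0L, seed) {
  if (!is.numeric(n) || n < 3) pgain_validation_error("n must be >= 3")
  if (maf <= 0 || maf > 0.5) {
    pgain_validation_error("maf must lie in (0, 0.5]")
  }
  if (shared_sd < 0 || noise_sd1 < 0 || noise_sd2 < 0) {
    pgain_validation_error("standard deviations must be >= 0")
  }
  if (noise_sd1 == 0 || noise_sd2 == 0) {
    pgain_degenerate_error(
      "each metabolite needs a positive residual SD (noise_sd1, noise_sd2)")
  }
  if (missing(seed)) pgain_validation_error("seed is required")
  structure(list(n = as.integer(n), maf = maf, beta1 = beta1,
                 beta2 = beta2, shared_sd = shared_sd,
                 noise_sd1 = noise_sd1, noise_sd2 = noise_sd2,
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [generator_spec()]; identical spec and seed give
#' an identical cohort. The planted metabolites are named `M1` and `M2`.
#'
#' At `beta1 = beta2 = 0` the implied correlation of the two
#' log-metabolites is
#' `shared_sd^2 / sqrt((shared_sd^2 + noise_sd1^2) (shared_sd^2 + noise_sd2^2))`.
#'
#' @param spec a [generator_spec()].
#' @return A [cohort_table()] with the genotype dosage as trait and the
#'   spec stored in `attr(, "ground_truth")`.
#' @examples
#' co <- generate_cohort(generator_spec(n = 200, beta1 = 0.25,
#'                                      beta2 = -0.25, seed = 7))
#' pgain_scan(co)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "generator_spec")) {
    pgain_validation_error("spec must be a generator_spec")
  }
  set.seed(spec$seed)
  n <- spec$n
  g <- stats::rbinom(n, 2L, spec$maf)
  u <- stats::rnorm(n, 0, spec$shared_sd)
  log_m1 <- spec$beta1 * g + u + stats::rnorm(n, 0, spec$noise_sd1)
  log_m2 <- spec$beta2 * g + u + stats::rnorm(n, 0, spec$noise_sd2)
  mets <- cbind(M1 = exp(log_m1), M2 = exp(log_m2))
  if (spec$n_null > 0L) {
    nulls <- matrix(exp(stats::rnorm(n * spec$n_null)), n, spec$n_null,
                    dimnames = list(NULL, paste0("N", seq_len(spec$n_null))))
    mets <- cbind(mets, nulls)
  }
  co <- cohort_table(mets, trait = g,
                     sample_ids = sprintf("S%05d", seq_len(n)))
  attr(co, "ground_truth") <- spec
  co
}
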