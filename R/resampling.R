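#' Dependence of the p-gain on sample size
#'
#' Repeated random subsampling (with replacement, i.e. bootstrap) of a
#' cohort at a series of sample sizes, recomputing the p-gain of one
#' metabolite pair per draw. For each size the median and first and third
#' quartiles of the log10 p-gain across replicates are reported, tracing
#' how the observed p-gain grows with cohort size. The defaults — sizes
#' 100 to 2000 and 1500 replicates — mirror the standard design of this
#' experiment.
#'
#' Replicates whose subsample has a constant trait (or is otherwise
#' degenerate) are skipped and counted; if more than 10 % of replicates at
#' any size are skipped, the run stops with an error.
#'
#' @param cohort a [cohort_table()].
#' @param pair character vector of two metabolite names.
#' @param sizes integer vector of subsample sizes, each >= 10.
#' @param n_reps replicates per size.
#' @param seed integer RNG seed.
#' @param replace draw with replacement (the default); `replace = FALSE`
#'   with `size` equal to the full cohort reproduces the full-cohort
#'   p-gain exactly.
#' @param log_single log-transform the single metabolites, as in
#'   [pgain_scan()].
#' @return data frame of class `pgain_subsample` with one row per size:
#'   `sample_size`, `median_log10_pgain`, `q1_log10_pgain`,
#'   `q3_log10_pgain`, `n_reps`, `n_skipped`. Quartiles are type-7
#'   order-statistic interpolation on the log10 scale.
#' @examples
#' co <- generate_cohort(generator_spec(n = 500, seed = 3))
#' pgain_vs_sample_size(co, c("M1", "M2"), sizes = c(50, 100),
#'                      n_reps = 20, seed = 1)
#' @export
pgain_vs_sample_size <- function(cohort, pair,
                                 sizes = c(100L, 500L, 1000L, 1500L, 2000L),
                                 n_reps = 1500L, seed, replace = TRUE,
                                 log_single = TRUE) {
  if (!inherits(cohort, "cohort_table")) {
    pgain_validation_error("cohort must be a cohort_table")
  }
  if (length(pair) != 2L || !all(pair %in% colnames(cohort$metabolites))) {
    pgain_validation_error("pair must name two metabolites in the cohort")
  }
  if (any(sizes < 10L)) pgain_validation_error("each size must be >= 10")
  if (missing(seed)) pgain_validation_error("seed is required")

  a <- cohort$metabolites[, pair[1L]]
  b <- cohort$metabolites[, pair[2L]]
  usable <- is.finite(a) & is.finite(b) & a > 0 & b > 0 &
    is.finite(cohort$trait)
  a <- a[usable]
  b <- b[usable]
  x <- cohort$trait[usable]
  n <- length(x)
  if (!replace && any(sizes > n)) {
    pgain_validation_error(
      "sizes cannot exceed the cohort size without replacement")
  }
  y1 <- if (log_single) log(a) else a
  y2 <- if (log_single) log(b) else b
  yr <- log(a) - log(b)

  set.seed(as.integer(seed))
  rows <- lapply(sizes, function(sz) {
    lg <- rep(NA_real_, n_reps)
    skipped <- 0L
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n, sz, replace = replace)
      xi <- x[idx]
      if (stats::var(xi) == 0 || stats::var(yr[idx]) == 0 ||
          stats::var(y1[idx]) == 0 || stats::var(y2[idx]) == 0) {
        skipped <- skipped + 1L
        next
      }
      lp1 <- fast_simple_log10p(xi, y1[idx])
      lp2 <- fast_simple_log10p(xi, y2[idx])
      lpr <- fast_simple_log10p(xi, yr[idx])
      lg[r] <- min(lp1, lp2) - lpr
    }
    if (skipped > 0.1 * n_reps) {
      pgain_degenerate_error(paste0(
        skipped, " of ", n_reps, " replicates at size ", sz,
        " were degenerate (> 10 %); the cohort is too small or the trait ",
        "too rare for this size"))
    }
    if (skipped > 0L) {
      message(skipped, " replicate(s) skipped at size ", sz,
              " (degenerate subsample)")
    }
    qs <- stats::quantile(lg[!is.na(lg)], c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
    data.frame(sample_size = sz, median_log10_pgain = qs[2L],
               q1_log10_pgain = qs[1L], q3_log10_pgain = qs[3L],
               n_reps = n_reps, n_skipped = skipped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("pgain_subsample", "data.frame")
  out
}

# simple OLS t-test p-value in log10 via the correlation identity;
# numerically identical to associate() without covariates
fast_simple_log10p <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(x, y)
  rho <- max(min(rho, 1), -1)
  tstat <- abs(rho) * sqrt((n - 2) / max(1 - rho^2, 0))
  log10_p_from_t(tstat, n - 2)
}
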