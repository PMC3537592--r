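#' Log-ratio of two metabolite concentration vectors
#'
#' Ratios are analysed on the natural-log scale, where
#' `log(a/b) = -log(b/a)`: the two orientations of a pair differ only in
#' sign, give identical regression p-values, and each unordered pair
#' therefore needs to be tested only once — halving the multiple-testing
#' burden of a ratio scan.
#'
#' @param a,b strictly positive, finite numeric vectors of equal length.
#' @return `log(a) - log(b)`, elementwise.
#' @examples
#' log_ratio(c(2, exp(1)), c(2, 1))  # 0, 1
#' @export
log_ratio <- function(a, b) {
  if (length(a) != length(b)) {
    pgain_validation_error("concentration vectors must have equal length")
  }
  bad <- which(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)
  if (length(bad)) {
    ids <- names(a)[bad] %||% as.character(bad)
    pgain_validation_error(paste0(
      "non-positive or non-finite concentrations in samples: ",
      paste(utils::head(ids, 10), collapse = ", "),
      if (length(bad) > 10) paste0(" (and ", length(bad) - 10, " more)")))
  }
  log(a) - log(b)
}

#' Association of a quantity with a trait by linear regression
#'
#' Ordinary least squares of the quantity `y` on the trait `x`, optionally
#' adjusting for covariates. The p-value of the trait coefficient is the
#' two-sided t-test, computed directly on the log scale from the log tail
#' of the t distribution — never by exponentiating and re-logging — so
#' associations far below the double-precision minimum (p ~ 1e-308) remain
#' finite in log10. This matters because p-gains spanning tens of orders of
#' magnitude are routine in metabolomics GWAS.
#'
#' Missing values are removed complete-case across `x`, `y` and the
#' covariates before fitting.
#'
#' @param x numeric trait vector (phenotype or genotype dosage).
#' @param y numeric quantity vector (a log-metabolite or log-ratio).
#' @param covariates optional numeric matrix, one row per sample.
#' @param quantity_name label stored in the result.
#' @return An object of class `pgain_assoc`: list with `quantity_name`,
#'   `log10_p` (log10 of the two-sided p-value, <= 0), `beta` (slope of
#'   `x`), `explained_variance` (incremental R-squared of `x` over the
#'   covariate-only model) and `n_used`.
#' @examples
#' set.seed(1)
#' x <- rbinom(100, 2, 0.3)
#' associate(x, 0.4 * x + rnorm(100))
#' @export
associate <- function(x, y, covariates = NULL, quantity_name = "quantity") {
  if (length(x) != length(y)) {
    pgain_validation_error("trait and quantity must have equal length")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(x)) {
      pgain_validation_error("covariates must have one row per sample")
    }
  }
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    keep <- keep & apply(is.finite(covariates), 1L, all)
  }
  x <- x[keep]
  y <- y[keep]
  cv <- if (is.null(covariates)) NULL else covariates[keep, , drop = FALSE]
  n <- length(x)
  npar <- 2L + if (is.null(cv)) 0L else ncol(cv)
  if (n < npar + 1L) {
    pgain_degenerate_error(paste0(
      "insufficient samples after complete-case filtering: n = ", n,
      ", need at least ", npar + 1L))
  }
  if (stats::var(x) == 0) {
    pgain_degenerate_error("trait is constant after filtering")
  }
  if (stats::var(y) == 0) {
    pgain_degenerate_error(paste0("quantity '", quantity_name,
                                  "' is constant after filtering"))
  }

  xm <- cbind(`(Intercept)` = 1, cv, trait = x)
  fit <- stats::lm.fit(xm, y)
  if (fit$rank < ncol(xm)) {
    pgain_degenerate_error(paste0(
      "rank-deficient design for quantity '", quantity_name,
      "' (trait collinear with covariates?)"))
  }
  df <- n - ncol(xm)
  rss <- sum(fit$residuals^2)
  beta <- fit$coefficients[["trait"]]
  # (X'X)^-1 from the QR factor; trait is the last (unpivoted-last) column
  R <- qr.R(fit$qr)
  xtxinv <- chol2inv(R)
  k <- which(colnames(R) == "trait")
  se <- sqrt(rss / df * xtxinv[k, k])
  tstat <- if (se > 0) beta / se else sign(beta) * Inf
  log10_p <- log10_p_from_t(tstat, df)

  tss <- sum((y - mean(y))^2)
  rss0 <- if (is.null(cv)) tss else {
    sum(stats::lm.fit(cbind(1, cv), y)$residuals^2)
  }
  ev <- max(0, min(1, (rss0 - rss) / tss))

  structure(list(quantity_name = quantity_name, log10_p = log10_p,
                 beta = beta, explained_variance = ev, n_used = n),
            class = "pgain_assoc")
}

#' @export
print.pgain_assoc <- function(x, ...) {
  cat("association: ", x$quantity_name,
      "  log10(p) = ", format(x$log10_p, digits = 6),
      "  beta = ", format(x$beta, digits = 4),
      "  R2 = ", format(x$explained_variance, digits = 4),
      "  n = ", x$n_used, "\n", sep = "")
  invisible(x)
}

# two-sided t-test p-value on the log10 scale; underflow-safe
log10_p_from_t <- function(tstat, df) {
  (log(2) + stats::pt(abs(tstat), df = df, lower.tail = FALSE,
                      log.p = TRUE)) / log(10)
}

#' The p-gain of a metabolite ratio, in log10
#'
#' The p-gain compares the strength of the ratio association with the
#' stronger of the two single-metabolite associations:
#' `p-gain = min(p(M1|X), p(M2|X)) / p(M1/M2|X)`. On the log10 scale this
#' is `min(log10 p1, log10 p2) - log10 p_ratio`, which stays finite for
#' p-gains far beyond double precision (observed values reach 1e66 and
#' more). The statistic is symmetric in M1 and M2.
#'
#' @param log10_p1,log10_p2 log10 p-values of the two single-metabolite
#'   associations (<= 0).
#' @param log10_p_ratio log10 p-value of the ratio association (<= 0).
#' @return log10 of the p-gain (vectorised).
#' @examples
#' compute_pgain(log10(1e-5), log10(1e-3), log10(1e-8))  # 3
#' @seealso [pgain_linear()] for a saturating linear-scale accessor,
#'   [pgain_tail_prob()] for the attached null p-value.
#' @export
compute_pgain <- function(log10_p1, log10_p2, log10_p_ratio) {
  for (v in list(log10_p1, log10_p2, log10_p_ratio)) {
    if (!is.numeric(v) || any(is.na(v)) || any(v > 0)) {
      pgain_domain_error(
        "log10 p-values must be <= 0 (p-values cannot exceed 1)")
    }
  }
  pmin(log10_p1, log10_p2) - log10_p_ratio
}

#' Linear-scale p-gain with overflow flag
#'
#' Converts a log10 p-gain back to the linear scale. Values beyond the
#' largest representable double are saturated at `.Machine$double.xmax`
#' and flagged, rather than returned as `Inf`.
#'
#' @param log10_pgain numeric vector of log10 p-gains.
#' @return data frame with columns `pgain` (linear scale, saturated) and
#'   `saturated` (logical).
#' @export
pgain_linear <- function(log10_pgain) {
  sat <- log10_pgain > log10(.Machine$double.xmax)
  val <- ifelse(sat, .Machine$double.xmax, 10^log10_pgain)
  data.frame(pgain = val, saturated = sat)
}

#' Scan all metabolite ratios for trait association
#'
#' For every unordered metabolite pair (or a supplied subset), fits three
#' regressions against the trait — each single metabolite (log-transformed
#' by default) and the log-ratio — and computes the log10 p-gain. The
#' number of ratio hypotheses actually tested, B, sets the Bonferroni
#' threshold: a pair is flagged significant when
#' `log10_pgain >= log10(B / (2 * alpha))`.
#'
#' Samples with missing or non-positive concentrations are excluded per
#' pair (complete-case) with a warning; a pair whose regressions are
#' degenerate is skipped with a recorded reason, never aborting the scan.
#' Ratio orientation does not affect the p-value or the flag.
#'
#' @param cohort a [cohort_table()].
#' @param alpha family-wise significance level in (0, 0.5].
#' @param pairs optional two-column character matrix or data frame of
#'   metabolite name pairs; defaults to all C(m, 2) unordered pairs.
#' @param log_single if `TRUE` (default), single metabolites enter the
#'   regression log-transformed, matching the log-scale ratio.
#' @return A data frame of class `pgain_scan`, one row per tested pair,
#'   sorted by decreasing `log10_pgain` (ties broken by pair name), with
#'   columns `pair_m1`, `pair_m2`, `log10_p_m1`, `log10_p_m2`,
#'   `log10_p_ratio`, `log10_pgain`, `pgain_linear`, `pgain_saturated`,
#'   `n_used`, `B`, `critical_log10`, `significant`. Skipped pairs and
#'   their reasons are in `attr(, "skipped")`.
#' @examples
#' co <- generate_cohort(generator_spec(n = 300, seed = 1))
#' pgain_scan(co, alpha = 0.05)
#' @export
pgain_scan <- function(cohort, alpha = 0.05, pairs = NULL,
                       log_single = TRUE) {
  if (!inherits(cohort, "cohort_table")) {
    pgain_validation_error("cohort must be a cohort_table")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
      alpha > 0.5) {
    pgain_domain_error("alpha must lie in (0, 0.5]")
  }
  mets <- cohort$metabolites
  m <- ncol(mets)
  if (m < 2L) pgain_validation_error("need at least 2 metabolites to scan")

  if (is.null(pairs)) {
    idx <- utils::combn(colnames(mets), 2L)
    pairs <- cbind(idx[1L, ], idx[2L, ])
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) {
      pgain_validation_error("pairs must have two columns of metabolite names")
    }
    missing <- setdiff(unique(c(pairs)), colnames(mets))
    if (length(missing)) {
      pgain_validation_error(paste0("unknown metabolites in pairs: ",
                                    paste(missing, collapse = ", ")))
    }
  }

  rows <- vector("list", nrow(pairs))
  skipped <- list()
  n_excluded_total <- 0L
  for (i in seq_len(nrow(pairs))) {
    m1 <- pairs[i, 1L]
    m2 <- pairs[i, 2L]
    a <- mets[, m1]
    b <- mets[, m2]
    usable <- is.finite(a) & is.finite(b) & a > 0 & b > 0
    n_excluded_total <- n_excluded_total + sum(!usable)
    res <- tryCatch({
      av <- a[usable]
      bv <- b[usable]
      xv <- cohort$trait[usable]
      cv <- if (is.null(cohort$covariates)) NULL else
        cohort$covariates[usable, , drop = FALSE]
      y1 <- if (log_single) log(av) else av
      y2 <- if (log_single) log(bv) else bv
      r1 <- associate(xv, y1, cv, m1)
      r2 <- associate(xv, y2, cv, m2)
      rr <- associate(xv, log_ratio(av, bv), cv, paste0(m1, "/", m2))
      data.frame(pair_m1 = m1, pair_m2 = m2,
                 log10_p_m1 = r1$log10_p, log10_p_m2 = r2$log10_p,
                 log10_p_ratio = rr$log10_p,
                 log10_pgain = compute_pgain(r1$log10_p, r2$log10_p,
                                             rr$log10_p),
                 n_used = rr$n_used, stringsAsFactors = FALSE)
    }, pgain_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(pair_m1 = m1, pair_m2 = m2, reason = res,
                   stringsAsFactors = FALSE)
      rows[i] <- list(NULL)
    } else {
      rows[[i]] <- res
    }
  }
  if (n_excluded_total > 0L) {
    warning(n_excluded_total,
            " sample values excluded pairwise (missing or non-positive ",
            "concentrations)", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(pair_m1 = character(), pair_m2 = character(),
               reason = character(), stringsAsFactors = FALSE)
  if (is.null(out) || nrow(out) == 0L) {
    pgain_degenerate_error("all metabolite pairs were skipped")
  }

  B <- nrow(out)  # ratio hypotheses actually tested
  critical_log10 <- pgain_critical_value(alpha, B, log10 = TRUE)
  lin <- pgain_linear(out$log10_pgain)
  out$pgain_linear <- lin$pgain
  out$pgain_saturated <- lin$saturated
  out$B <- B
  out$critical_log10 <- critical_log10
  out$significant <- out$log10_pgain >= critical_log10
  ord <- order(-out$log10_pgain, out$pair_m1, out$pair_m2)
  out <- out[ord, c("pair_m1", "pair_m2", "log10_p_m1", "log10_p_m2",
                    "log10_p_ratio", "log10_pgain", "pgain_linear",
                    "pgain_saturated", "n_used", "B", "critical_log10",
                    "significant")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("pgain_scan", "data.frame")
  out
}
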