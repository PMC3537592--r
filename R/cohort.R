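#' Assemble a sample-aligned cohort table
#'
#' A `cohort_table` bundles the inputs of a ratio association scan: a
#' samples x metabolites concentration matrix, one numeric trait per sample
#' (a continuous phenotype or an additive genotype dosage in \[0, 2\]) and
#' optional numeric covariates. All components are aligned on `sample_ids`.
#' Concentrations may contain missing or non-positive entries; these are
#' excluded per test (complete-case, pairwise) by [pgain_scan()], not here.
#'
#' @param metabolites numeric matrix or data frame of concentrations,
#'   samples in rows, named metabolite columns.
#' @param trait numeric vector, one value per sample.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to the row names of `metabolites`, or `S1..Sn`.
#' @param covariates optional numeric matrix or data frame of per-sample
#'   covariates, named columns.
#' @return An object of class `cohort_table`: a list with elements
#'   `sample_ids`, `metabolites` (matrix), `trait`, `covariates`
#'   (matrix or `NULL`).
#' @examples
#' m <- matrix(rlnorm(40), 20, 2, dimnames = list(NULL, c("M1", "M2")))
#' cohort_table(m, trait = rbinom(20, 2, 0.3))
#' @export
cohort_table <- function(metabolites, trait, sample_ids = NULL,
                         covariates = NULL) {
  metabolites <- as.matrix(metabolites)
  if (!is.numeric(metabolites)) {
    pgain_validation_error("metabolite concentrations must be numeric")
  }
  n <- nrow(metabolites)
  if (is.null(colnames(metabolites))) {
    pgain_validation_error("metabolite columns must be named")
  }
  if (anyDuplicated(colnames(metabolites))) {
    pgain_validation_error(paste0(
      "duplicated metabolite names: ",
      paste(unique(colnames(metabolites)[duplicated(colnames(metabolites))]),
            collapse = ", ")))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(metabolites) %||% paste0("S", seq_len(n))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) {
    pgain_validation_error("sample_ids length does not match metabolite rows")
  }
  if (anyDuplicated(sample_ids)) {
    pgain_validation_error(paste0(
      "duplicated sample IDs: ",
      paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (!is.numeric(trait) || length(trait) != n) {
    pgain_validation_error("trait must be a numeric vector, one per sample")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates) || nrow(covariates) != n) {
      pgain_validation_error(
        "covariates must be numeric with one row per sample")
    }
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("C", seq_len(ncol(covariates)))
    }
  }
  rownames(metabolites) <- sample_ids
  structure(list(sample_ids = sample_ids, metabolites = metabolites,
                 trait = as.numeric(trait), covariates = covariates),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table: ", length(x$sample_ids), " samples, ",
      ncol(x$metabolites), " metabolites (",
      paste(utils::head(colnames(x$metabolites), 5), collapse = ", "),
      if (ncol(x$metabolites) > 5) ", ..." else "", ")\n", sep = "")
  cat("trait range: [", format(min(x$trait, na.rm = TRUE)), ", ",
      format(max(x$trait, na.rm = TRUE)), "]",
      if (!is.null(x$covariates))
        paste0("; ", ncol(x$covariates), " covariates"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$metabolites)
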