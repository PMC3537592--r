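#' Read a delimited metabolite, trait, covariate or pairs table
#'
#' Tables are plain delimited text. The delimiter is inferred from the
#' file extension (`.tsv`/`.txt` tab, `.csv` comma) and can be overridden.
#' Schemas by kind:
#' \describe{
#'   \item{metabolites}{first column sample ID, remaining named numeric
#'     metabolite columns.}
#'   \item{trait}{columns `sample_id` and `trait` (or any two columns:
#'     first ID, second numeric trait).}
#'   \item{covariates}{first column sample ID, remaining numeric columns.}
#'   \item{pairs}{two columns of metabolite names, no sample IDs.}
#' }
#' Duplicate sample IDs and non-numeric cells are rejected with errors
#' naming the offending rows or columns.
#'
#' @param path file path.
#' @param kind one of `"metabolites"`, `"trait"`, `"covariates"`,
#'   `"pairs"`.
#' @param delim delimiter override (single character); default inferred
#'   from the extension.
#' @return For `pairs`, a two-column character matrix. Otherwise a numeric
#'   matrix (metabolites, covariates) or named numeric vector (trait) with
#'   sample IDs as row/element names.
#' @export
read_table <- function(path, kind = c("metabolites", "trait",
                                      "covariates", "pairs"),
                       delim = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    pgain_validation_error(paste0("file not found: ", path))
  }
  delim <- delim %||% infer_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    pgain_validation_error(paste0(
      "table ", path, " must have a header and at least two columns"))
  }
  if (kind == "pairs") {
    return(as.matrix(df[, 1:2]))
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    pgain_validation_error(paste0(
      "duplicated sample IDs in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  vals <- df[, -1L, drop = FALSE]
  nonnum <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(nonnum)) {
    pgain_validation_error(paste0(
      "non-numeric values in ", path, ", column(s): ",
      paste(nonnum, collapse = ", ")))
  }
  if (kind == "trait") {
    tr <- as.numeric(vals[[1L]])
    names(tr) <- ids
    return(tr)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

infer_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read and align a cohort from delimited files
#'
#' Reads a metabolite table and a trait table (optionally covariates),
#' intersects their sample IDs and returns a [cohort_table()]. The number
#' of samples dropped from each file by the intersection is reported via
#' `message()`; an empty intersection is an error.
#'
#' @param metabolites_file,trait_file,covariates_file file paths;
#'   `covariates_file` optional.
#' @param delim delimiter override applied to all files.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(metabolites_file, trait_file,
                        covariates_file = NULL, delim = NULL) {
  mets <- read_table(metabolites_file, "metabolites", delim)
  trait <- read_table(trait_file, "trait", delim)
  cov <- if (is.null(covariates_file)) NULL else
    read_table(covariates_file, "covariates", delim)
  ids <- intersect(rownames(mets), names(trait))
  if (!is.null(cov)) ids <- intersect(ids, rownames(cov))
  if (length(ids) == 0L) {
    pgain_validation_error(
      "no sample IDs shared between metabolite and trait tables")
  }
  dropped <- c(metabolites = nrow(mets) - length(ids),
               trait = length(trait) - length(ids),
               covariates = if (!is.null(cov)) nrow(cov) - length(ids))
  if (any(dropped > 0L)) {
    message("sample ID intersection: ", length(ids), " kept; dropped ",
            paste(paste0(dropped[dropped > 0L], " from ",
                         names(dropped)[dropped > 0L]), collapse = ", "))
  }
  cohort_table(mets[ids, , drop = FALSE], trait = unname(trait[ids]),
               sample_ids = ids,
               covariates = if (is.null(cov)) NULL else
                 cov[ids, , drop = FALSE])
}

#' Write a result table as TSV
#'
#' Writes any of the package's result data frames (scan records,
#' subsample summaries, quantile tables) as tab-separated text with a
#' header and no row names.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed, package version and MD5 checksums of
#' the input files next to a result file, for provenance.
#'
#' @param path manifest path (JSON).
#' @param config named list of configuration values (including the seed).
#' @param inputs character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, inputs = character()) {
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    package = "pgain",
    version = as.character(utils::packageVersion("pgain")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
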