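#' Parse the TCGA sample-type suffix from a barcode
#'
#' The sample-type code is the final dash-delimited token of the barcode
#' ("01" = primary solid tumor). Barcodes without a dash yield `NA`.
#'
#' @param barcode character vector of sample barcodes.
#' @return character vector of suffix codes.
#' @examples
#' sample_type_code(c("TCGA-AA-0001-01", "TCGA-AA-0002-06"))
#' @export
sample_type_code <- function(barcode) {
  has_dash <- grepl("-", barcode, fixed = TRUE)
  out <- rep(NA_character_, length(barcode))
  out[has_dash] <- sub(".*-", "", barcode[has_dash])
  out
}

#' Build or read a clinical metadata table
#'
#' Clinical covariates keyed by sample barcode: gender, race, ethnicity,
#' and the cohort label (`"PANNET"` or `"PGL"`). The sample-type code is
#' parsed from the barcode suffix if not supplied. Missing covariate
#' values are `NA`.
#'
#' @param sample character vector of unique sample barcodes.
#' @param cohort cohort label per sample.
#' @param gender,race,ethnicity covariates per sample (`NA` = missing).
#' @param sample_type_code per-sample type code; parsed from the barcode
#'   suffix when `NULL`.
#' @return A `data.frame` of class `clinical_table` with columns
#'   `sample`, `sample_type_code`, `gender`, `race`, `ethnicity`, `cohort`.
#' @export
clinical_table <- function(sample, cohort,
                           gender = NA_character_, race = NA_character_,
                           ethnicity = NA_character_,
                           sample_type_code = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample))
    stop("duplicate sample ids in clinical table", call. = FALSE)
  n <- length(sample)
  if (is.null(sample_type_code))
    sample_type_code <- mirconsensus::sample_type_code(sample)
  out <- data.frame(
    sample = sample,
    sample_type_code = rep_len(as.character(sample_type_code), n),
    gender = rep_len(as.character(gender), n),
    race = rep_len(as.character(race), n),
    ethnicity = rep_len(as.character(ethnicity), n),
    cohort = rep_len(as.character(cohort), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' @rdname clinical_table
#' @param path TSV file with named columns `sample`, `gender`, `race`,
#'   `ethnicity`, `cohort` (extra columns are kept).
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "", na.strings = c("NA", ""))
  need <- c("sample", "cohort")
  if (!all(need %in% colnames(raw)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  get <- function(col) if (col %in% colnames(raw)) raw[[col]] else NA_character_
  clinical_table(sample = raw[["sample"]], cohort = raw[["cohort"]],
                 gender = get("gender"), race = get("race"),
                 ethnicity = get("ethnicity"),
                 sample_type_code = if ("sample_type_code" %in% colnames(raw))
                   raw[["sample_type_code"]] else NULL)
}

#' Join an expression matrix with clinical metadata
#'
#' Restricts both sides to the intersection of their sample ids and
#' returns them as one bundle with consistent sample ordering (the
#' expression column order of the retained samples). Samples present on
#' only one side are dropped and recorded in the bundle.
#'
#' @param m an [expr_matrix()].
#' @param clinical a [clinical_table()].
#' @return An object of class `cohort_bundle`: a list with elements
#'   `expression` and `clinical`, plus `dropped_expression` /
#'   `dropped_clinical` (the ids removed from each side).
#' @export
merge_clinical <- function(m, clinical) {
  stopifnot(inherits(m, "expr_matrix"), inherits(clinical, "clinical_table"))
  keep <- intersect(colnames(m), clinical$sample)
  if (length(keep) == 0L)
    stop("no samples shared between expression matrix and clinical table",
         call. = FALSE)
  keep <- colnames(m)[colnames(m) %in% keep]   # expression order
  cl <- clinical[match(keep, clinical$sample), , drop = FALSE]
  rownames(cl) <- NULL
  out <- list(
    expression = m[, keep],
    clinical = cl,
    dropped_expression = setdiff(colnames(m), keep),
    dropped_clinical = setdiff(clinical$sample, keep)
  )
  class(out) <- "cohort_bundle"
  out
}

#' @export
print.cohort_bundle <- function(x, ...) {
  tab <- table(x$clinical$cohort)
  cat(sprintf("<cohort_bundle> %d features x %d samples\n",
              nrow(x$expression), ncol(x$expression)))
  cat("  cohorts:", paste(sprintf("%s (n=%d)", names(tab), tab),
                          collapse = ", "), "\n")
  kinds <- table(feature_kind(x$expression))
  cat("  features:", paste(sprintf("%s: %d", names(kinds), kinds),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a bundle
#' @param b a `cohort_bundle`.
#' @return integer sample count.
#' @export
n_samples <- function(b) {
  stopifnot(inherits(b, "cohort_bundle"))
  ncol(b$expression)
}

#' Subset a bundle to a set of samples
#' @param b a `cohort_bundle`.
#' @param samples barcodes to keep (order follows the bundle).
#' @return the restricted `cohort_bundle`.
#' @export
subset_samples <- function(b, samples) {
  stopifnot(inherits(b, "cohort_bundle"))
  keep <- colnames(b$expression) %in% samples
  if (!any(keep)) stop("no samples left after subsetting", call. = FALSE)
  out <- list(expression = b$expression[, keep],
              clinical = b$clinical[keep, , drop = FALSE],
              dropped_expression = character(0),
              dropped_clinical = character(0))
  rownames(out$clinical) <- NULL
  class(out) <- "cohort_bundle"
  out
}

#' Keep only primary-tumor samples
#'
#' Removes every sample whose TCGA sample-type code (the final
#' dash-delimited barcode token) is not `"01"`, the primary-solid-tumor
#' code. The feature dimension is never changed.
#'
#' @param b a `cohort_bundle`.
#' @param code the sample-type code to keep, default `"01"`.
#' @return The filtered `cohort_bundle`; removed barcodes are recorded in
#'   the `"removed_nonprimary"` attribute.
#' @export
filter_primary <- function(b, code = "01") {
  stopifnot(inherits(b, "cohort_bundle"))
  stc <- b$clinical$sample_type_code
  if (all(is.na(stc)))
    stop("no sample carries a parseable sample-type suffix", call. = FALSE)
  keep <- !is.na(stc) & stc == code
  if (!any(keep))
    stop(sprintf(
      "primary-tumor filter removed all %d samples (0 with code '%s')",
      length(stc), code), call. = FALSE)
  out <- subset_samples(b, b$clinical$sample[keep])
  attr(out, "removed_nonprimary") <- b$clinical$sample[!keep]
  out
}
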