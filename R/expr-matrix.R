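#' Expression matrix container
#'
#' A thin S3 wrapper around a numeric features-by-samples matrix of
#' log2(RPM+1) expression values. Row names are feature identifiers
#' (miRNA names such as `"hsa-miR-141-3p"` or gene symbols), column names
#' are sample barcodes, and every feature carries a kind tag
#' (`"gene"` or `"mirna"`) so that downstream stages can select one
#' feature view.
#'
#' @param values numeric matrix, features in rows, samples in columns;
#'   must have unique, non-empty row and column names.
#' @param kind character scalar or vector of per-feature kind tags, each
#'   `"gene"` or `"mirna"`. A scalar is recycled to all features.
#' @return An object of class `expr_matrix`: the value matrix with a
#'   `kind` attribute.
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'                         dimnames = list(paste0("miR-", 1:3), c("s1", "s2"))),
#'                  kind = "mirna")
#' feature_kind(m)
#' @export
expr_matrix <- function(values, kind = "mirna") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("`values` must have feature row names and sample column names",
         call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  kind <- as.character(kind)
  if (length(kind) == 1L) kind <- rep(kind, nrow(values))
  if (length(kind) != nrow(values))
    stop("`kind` must be length 1 or nrow(values)", call. = FALSE)
  if (!all(kind %in% c("gene", "mirna")))
    stop("feature kind must be 'gene' or 'mirna'", call. = FALSE)
  structure(values, kind = kind, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
feature_kind <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  attr(m, "kind")
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- attr(x, "kind")
  names(kind) <- rownames(x)
  out <- unclass(x)[i, j, drop = FALSE]
  expr_matrix(out, kind = kind[rownames(out)])
}

#' @export
print.expr_matrix <- function(x, ...) {
  kinds <- table(attr(x, "kind"))
  cat(sprintf("<expr_matrix> %d features x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
  n_show <- min(5L, nrow(x))
  m_show <- min(4L, ncol(x))
  print(unclass(x)[seq_len(n_show), seq_len(m_show), drop = FALSE], ...)
  if (nrow(x) > n_show || ncol(x) > m_show) cat("...\n")
  invisible(x)
}

#' Combine two expression matrices by row
#'
#' Stacks a gene block and a miRNA block measured on the same samples,
#' the merge step that produces the joint table used for morphing views.
#' Samples are matched by id; both matrices must cover the same samples.
#'
#' @param a,b `expr_matrix` objects over identical sample sets.
#' @return An `expr_matrix` with the rows of `a` followed by the rows of `b`.
#' @export
bind_features <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  if (!setequal(colnames(a), colnames(b)))
    stop("sample ids of the two blocks differ", call. = FALSE)
  b <- b[, colnames(a)]
  expr_matrix(rbind(unclass(a), unclass(b)),
              kind = c(feature_kind(a), feature_kind(b)))
}

#' Read a Xena-style expression matrix from TSV
#'
#' Parses the tab-separated dialect used by the Xena browser hub exports:
#' a header row of sample barcodes, first column of feature identifiers,
#' one sample per remaining column, values in log2(RPM+1). Cells that do
#' not parse as numbers become `NA` and are removed later by
#' [curate_expression()].
#'
#' @param path path to the TSV file.
#' @param kind feature kind tag for all rows, `"gene"` or `"mirna"`.
#' @param samples_in_rows set `TRUE` for the transposed dialect
#'   (one sample per row, features in columns).
#' @return An [expr_matrix()]. Unparseable cells are `NA`.
#' @export
read_expression_tsv <- function(path, kind = c("mirna", "gene"),
                                samples_in_rows = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 2L)) < 2L)
    stop("empty expression file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty expression file: ", path, call. = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  cols <- colnames(raw)[-1L]
  if (anyDuplicated(cols))
    stop("duplicate sample columns in ", path, ": ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "), call. = FALSE)
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, cols))
  if (samples_in_rows) {
    vals <- t(vals)
  }
  expr_matrix(vals, kind = kind)
}

#' Write an expression matrix as Xena-style TSV
#'
#' @param m an `expr_matrix`.
#' @param path output path; UTF-8, tab-delimited, header row of barcodes.
#' @param id_column name for the leading feature-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path, id_column = "feature") {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop features with invalid values
#'
#' Curates an expression matrix by removing every feature row that
#' contains at least one invalid value: `NA`, `NaN`, or infinity
#' (unparseable cells have already become `NA` at read time). Samples are
#' never removed.
#'
#' @param m an [expr_matrix()].
#' @return The curated `expr_matrix`; the ids of removed features are
#'   attached as attribute `"dropped"` and retrievable with
#'   [curation_report()].
#' @export
curate_expression <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  bad <- apply(!is.finite(unclass(m)), 1L, any)
  if (all(bad))
    stop("curation removed every feature: all ", nrow(m),
         " rows contain invalid (missing or non-finite) values",
         call. = FALSE)
  out <- m[!bad, ]
  attr(out, "dropped") <- rownames(m)[bad]
  out
}

#' @rdname curate_expression
#' @export
curation_report <- function(m) {
  dropped <- attr(m, "dropped")
  data.frame(feature = if (is.null(dropped)) character(0) else dropped,
             reason = rep("invalid value", length(dropped)),
             stringsAsFactors = FALSE)
}

#' @rdname curate_expression
#' @param path output path for the TSV curation report.
#' @export
write_curation_report <- function(m, path) {
  utils::write.table(curation_report(m), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Center each feature across all samples
#'
#' Per-feature mean centering on the log2 scale, matching the
#' mean-normalized-per-gene convention of the upstream HiSeq tables.
#' Input that is already centered passes through unchanged (the operation
#' is idempotent), so either convention can be fed to the pipeline; the
#' choice is recorded in the `"centered"` attribute.
#'
#' @param m an [expr_matrix()].
#' @return The centered `expr_matrix` with attribute `centered = TRUE`.
#' @export
center_features <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  out <- expr_matrix(unclass(m) - rowMeans(unclass(m)),
                     kind = feature_kind(m))
  attr(out, "centered") <- TRUE
  out
}
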