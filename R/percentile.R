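#' Control-free percentile normalization
#'
#' Maps every measurement to its rank-based percentile within its own
#' dataset, so independently processed datasets become comparable
#' without shared control samples. With `pool = "global"` (default) each
#' cell's percentile is computed against the pooled distribution of all
#' expression values across all samples in the dataset; with
#' `pool = "per_feature"` ranks are computed within each feature row.
#' Ties take the midrank and percentiles use the `(rank - 0.5) / N`
#' convention, which keeps values strictly inside (0, 1) and maps an
#' all-tied dataset to 0.5.
#'
#' Because only ranks enter, any strictly increasing transform of the
#' raw values (a change of normalization pipeline, for instance) leaves
#' the output unchanged — the property motivating the method.
#'
#' @param m a curated [expr_matrix()] (no missing values).
#' @param pool `"global"` or `"per_feature"`.
#' @param dataset_id label recorded with the matrix.
#' @return An object of class `percentile_matrix`: the matrix of
#'   percentiles in (0, 1), with attributes `pool` and `dataset_id`.
#' @export
percentile_normalize <- function(m, pool = c("global", "per_feature"),
                                 dataset_id = "dataset") {
  stopifnot(inherits(m, "expr_matrix"))
  pool <- match.arg(pool)
  v <- unclass(m)
  if (length(v) == 0L) stop("empty expression matrix", call. = FALSE)
  if (any(!is.finite(v)))
    stop("matrix contains invalid values; curate it first", call. = FALSE)
  p <- if (pool == "global") {
    matrix((rank(v, ties.method = "average") - 0.5) / length(v),
           nrow = nrow(v), dimnames = dimnames(v))
  } else {
    t(apply(v, 1L, function(r) (rank(r, ties.method = "average") - 0.5) /
              length(r)))
  }
  dimnames(p) <- dimnames(v)
  structure(p, kind = feature_kind(m), pool = pool, dataset_id = dataset_id,
            class = c("percentile_matrix", "expr_matrix", "matrix", "array"))
}

#' @export
print.percentile_matrix <- function(x, ...) {
  cat(sprintf("<percentile_matrix> '%s', %d features x %d samples, pool = %s\n",
              attr(x, "dataset_id"), nrow(x), ncol(x), attr(x, "pool")))
  invisible(x)
}

#' Group contrast on percentile-normalized values
#'
#' For each requested marker, compares its percentile values between two
#' sample groups: one-way ANOVA on the percentiles (consistent with the
#' confirmation stage) or a Wilcoxon rank-sum test, plus per-group
#' median and IQR summaries and the direction of the difference.
#' Features absent from the matrix are reported as missing rows, never
#' an error.
#'
#' @param p a [percentile_normalize()] result.
#' @param labels two-group factor over the samples of `p`.
#' @param features marker ids to test (default: all features).
#' @param test `"anova"` (default) or `"ranksum"`.
#' @return data.frame of class `cross_dataset_comparison`: one row per
#'   feature with group medians/IQRs, statistic, `p`, and `direction`
#'   (`"up"` = higher in the first group, `"down"`, `"none"`).
#' @export
compare_groups <- function(p, labels, features = rownames(p),
                           test = c("anova", "ranksum")) {
  stopifnot(inherits(p, "percentile_matrix"))
  test <- match.arg(test)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) == 0L)) stop("both groups must be non-empty",
                                     call. = FALSE)
  g <- levels(labels)
  rows <- lapply(features, function(f) {
    if (!f %in% rownames(p))
      return(data.frame(feature = f, missing = TRUE,
                        median_1 = NA_real_, iqr_1 = NA_real_,
                        median_2 = NA_real_, iqr_2 = NA_real_,
                        statistic = NA_real_, p = NA_real_,
                        direction = NA_character_,
                        stringsAsFactors = FALSE))
    v <- unclass(p)[f, ]
    med <- tapply(v, labels, stats::median)
    iqr <- tapply(v, labels, stats::IQR)
    if (test == "anova") {
      a <- anova_two_group(v, labels)
      stat <- a$F
      pv <- a$p
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v[labels == g[1L]],
                                                v[labels == g[2L]]))
      stat <- unname(wt$statistic)
      pv <- wt$p.value
    }
    delta <- med[[g[1L]]] - med[[g[2L]]]
    data.frame(feature = f, missing = FALSE,
               median_1 = med[[g[1L]]], iqr_1 = iqr[[g[1L]]],
               median_2 = med[[g[2L]]], iqr_2 = iqr[[g[2L]]],
               statistic = stat, p = if (is.na(pv)) NA_real_ else pv,
               direction = if (is.na(pv) || pv > 0.05 || delta == 0) "none"
               else if (delta > 0) "up" else "down",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[3:6] <- c(paste0("median_", g), paste0("iqr_", g))[c(1, 3, 2, 4)]
  attr(out, "groups") <- g
  attr(out, "test") <- test
  attr(out, "dataset_id") <- attr(p, "dataset_id")
  class(out) <- c("cross_dataset_comparison", "data.frame")
  out
}

#' Cross-dataset marker confirmation
#'
#' The validation stage for markers discovered in one study: each
#' dataset is percentile-normalized independently (never pooled across
#' datasets), then the two cohorts are contrasted on the concatenated
#' percentile values, with per-dataset group summaries retained. Because
#' each dataset contributes only ranks relative to itself, datasets
#' processed with different platforms or normalization pipelines can be
#' combined.
#'
#' @param datasets named list of `cohort_bundle`s, each one independently
#'   processed dataset; names are the dataset ids. At least 2.
#' @param features marker ids to confirm.
#' @param pool,test passed to [percentile_normalize()] /
#'   [compare_groups()].
#' @param kind feature kind used, default `"mirna"`.
#' @return list of class `cross_dataset_report`: `comparison` (the
#'   pooled contrast, one row per feature), `per_dataset` (per-dataset
#'   group medians), `percentiles` (long data.frame with `dataset`
#'   retained), `test`, `pool`.
#' @export
cross_dataset_report <- function(datasets, features,
                                 pool = c("global", "per_feature"),
                                 test = c("anova", "ranksum"),
                                 kind = "mirna") {
  pool <- match.arg(pool)
  test <- match.arg(test)
  if (!is.list(datasets) || length(datasets) < 2L)
    stop("at least 2 independently processed datasets are required",
         call. = FALSE)
  if (is.null(names(datasets)) || any(names(datasets) == ""))
    stop("`datasets` must be a named list (dataset ids)", call. = FALSE)
  pm <- lapply(names(datasets), function(id) {
    b <- datasets[[id]]
    stopifnot(inherits(b, "cohort_bundle"))
    keep <- feature_kind(b$expression) == kind
    percentile_normalize(b$expression[keep, ], pool = pool, dataset_id = id)
  })
  names(pm) <- names(datasets)

  long <- do.call(rbind, lapply(names(pm), function(id) {
    p <- pm[[id]]
    cl <- datasets[[id]]$clinical
    have <- intersect(features, rownames(p))
    if (length(have) == 0L) return(NULL)
    do.call(rbind, lapply(have, function(f)
      data.frame(dataset = id, feature = f, sample = colnames(p),
                 cohort = cl$cohort[match(colnames(p), cl$sample)],
                 percentile = unclass(p)[f, ], stringsAsFactors = FALSE)))
  }))
  rownames(long) <- NULL
  if (is.null(long) || length(unique(long$cohort)) != 2L)
    stop("the combined datasets must cover the requested features in ",
         "exactly two cohorts", call. = FALSE)

  g <- sort(unique(long$cohort))
  comparison <- do.call(rbind, lapply(features, function(f) {
    d <- long[long$feature == f, ]
    if (nrow(d) == 0L)
      return(data.frame(feature = f, missing = TRUE, statistic = NA_real_,
                        p = NA_real_, direction = NA_character_,
                        stringsAsFactors = FALSE))
    lab <- factor(d$cohort, levels = g)
    if (test == "anova") {
      a <- anova_two_group(d$percentile, lab)
      stat <- a$F
      pv <- a$p
    } else {
      wt <- suppressWarnings(stats::wilcox.test(
        d$percentile[lab == g[1L]], d$percentile[lab == g[2L]]))
      stat <- unname(wt$statistic)
      pv <- wt$p.value
    }
    delta <- stats::median(d$percentile[lab == g[1L]]) -
      stats::median(d$percentile[lab == g[2L]])
    data.frame(feature = f, missing = FALSE, statistic = stat, p = pv,
               direction = if (is.na(pv) || pv > 0.05 || delta == 0) "none"
               else if (delta > 0) "up" else "down",
               stringsAsFactors = FALSE)
  }))

  agg <- stats::aggregate(percentile ~ dataset + cohort + feature, long,
                          stats::median)
  names(agg)[names(agg) == "percentile"] <- "median_percentile"

  structure(list(comparison = comparison, per_dataset = agg,
                 percentiles = long, groups = g, test = test, pool = pool),
            class = "cross_dataset_report")
}

#' @export
print.cross_dataset_report <- function(x, ...) {
  cat(sprintf("<cross_dataset_report> %d features, %d datasets, %s on %s percentiles\n",
              nrow(x$comparison), length(unique(x$percentiles$dataset)),
              x$test, x$pool))
  cat(sprintf("  direction 'up' = higher in %s\n", x$groups[1L]))
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Export a cross-dataset comparison as TSV
#'
#' Columns: dataset, feature, per-group medians, statistic, p, direction.
#'
#' @param x a `cross_dataset_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation_tsv <- function(x, path) {
  stopifnot(inherits(x, "cross_dataset_report"))
  wide <- stats::reshape(x$per_dataset, idvar = c("dataset", "feature"),
                         timevar = "cohort", direction = "wide")
  out <- merge(wide, x$comparison, by = "feature", all.x = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
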