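#' Demographic strata for the consensus analysis
#'
#' Splits a primary-filtered bundle into the five analysis groups used to
#' guard marker selection against cohort composition bias:
#'
#' * `all_primary` — every primary-tumor sample;
#' * `male`, `female` — split by gender, protecting against the unequal
#'   gender proportions of the larger cohort;
#' * `white` — race `"white"` (the race of every PANNET sample);
#' * `not_hispanic_or_latino` — ethnicity `"not hispanic or latino"`
#'   (6 of the 7 PANNET samples; the unclassified one is excluded by the
#'   strict predicate).
#'
#' Every stratum is a subset of `all_primary`. A stratum in which either
#' cohort has fewer than 2 samples cannot support the downstream ranking
#' and ANOVA and is marked unusable (with a warning); the consensus run
#' then degrades to the usable strata.
#'
#' @param b a `cohort_bundle`, already primary-filtered.
#' @return A named list of `cohort_bundle`s, one per stratum, with a
#'   logical `"usable"` attribute (named by stratum).
#' @export
build_strata <- function(b) {
  stopifnot(inherits(b, "cohort_bundle"))
  cl <- b$clinical
  preds <- list(
    all_primary = rep(TRUE, nrow(cl)),
    male = !is.na(cl$gender) & cl$gender == "male",
    female = !is.na(cl$gender) & cl$gender == "female",
    white = !is.na(cl$race) & cl$race == "white",
    not_hispanic_or_latino = !is.na(cl$ethnicity) &
      cl$ethnicity == "not hispanic or latino"
  )
  usable <- logical(length(preds))
  names(usable) <- names(preds)
  strata <- vector("list", length(preds))
  names(strata) <- names(preds)
  for (nm in names(preds)) {
    keep <- preds[[nm]]
    if (!any(keep)) {
      usable[nm] <- FALSE
      strata[nm] <- list(NULL)
      next
    }
    sub <- subset_samples(b, cl$sample[keep])
    sizes <- table(sub$clinical$cohort)
    usable[nm] <- length(sizes) == 2L && min(sizes) >= 2L
    strata[[nm]] <- sub
  }
  if (!all(usable))
    warning("unusable strata (need >= 2 samples per cohort): ",
            paste(names(usable)[!usable], collapse = ", "), call. = FALSE)
  attr(strata, "usable") <- usable
  strata
}

#' One-way ANOVA for a two-group expression contrast
#'
#' Classic fixed-effects one-way analysis of variance of one feature's
#' values across two groups, via `stats::oneway.test(var.equal = TRUE)`;
#' for two groups the F statistic equals the square of the pooled-variance
#' t statistic. Per-group means and standard deviations are reported
#' alongside. When both groups have zero variance and equal means the F
#' statistic is undefined and reported as `NA`.
#'
#' @param values numeric vector, one value per sample.
#' @param labels two-group factor (or coercible) of the same length.
#' @return list of class `anova_two_group`: `F`, `p`, `df_between`,
#'   `df_within`, `group_means`, `group_sds`, `groups`.
#' @export
anova_two_group <- function(values, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two groups required, got ", nlevels(labels), call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("each group needs >= 2 samples for a within-group variance",
         call. = FALSE)
  gm <- tapply(values, labels, mean)
  gs <- tapply(values, labels, stats::sd)
  if (all(gs == 0)) {
    if (diff(range(gm)) == 0) {
      ft <- list(statistic = NA_real_, p.value = NA_real_)
      note <- "zero within-group variance and equal means: F undefined"
    } else {
      ft <- list(statistic = Inf, p.value = 0)
      note <- "zero within-group variance with unequal means"
    }
  } else {
    tst <- stats::oneway.test(values ~ labels, var.equal = TRUE)
    ft <- list(statistic = unname(tst$statistic), p.value = tst$p.value)
    note <- NA_character_
  }
  structure(list(F = ft$statistic, p = ft$p.value,
                 df_between = nlevels(labels) - 1L,
                 df_within = length(values) - nlevels(labels),
                 group_means = gm, group_sds = gs,
                 groups = levels(labels), note = note),
            class = "anova_two_group")
}

#' @export
print.anova_two_group <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p %s\n",
              x$df_between, x$df_within,
              format(x$F, digits = 4), format_pvalue(x$p)))
  for (g in x$groups)
    cat(sprintf("  %s: %.3g +/- %.3g\n", g, x$group_means[[g]], x$group_sds[[g]]))
  if (!is.na(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

format_pvalue <- function(p, floor = 1e-4) {
  if (is.na(p)) return("= NA")
  if (p < floor) sprintf("< %.4f", floor) else sprintf("= %.4g", p)
}

#' Stratified consensus marker selection with ANOVA confirmation
#'
#' The full selection pipeline: apply the primary-tumor filter, build the
#' five demographic strata, and in each usable stratum standardize the
#' miRNA features, estimate the characteristic direction between the two
#' cohorts, and take its top-`k` list. A feature is selected when it
#' appears in the top-`k` list of at least `min_lists` usable strata
#' (default: all of them — strict intersection). Each selected marker is
#' then confirmed by one-way ANOVA on the pooled `all_primary` stratum,
#' reported as per-cohort mean +/- sd and the raw p-value, with
#' Benjamini-Hochberg adjusted p-values (across the selected set) in an
#' adjacent column.
#'
#' The ranking fit is deterministic; `seed` is recorded in the provenance
#' for workflows that add stochastic stages (e.g. embedding views).
#'
#' @param b a two-cohort `cohort_bundle` (primary filter applied
#'   internally when non-primary samples are present).
#' @param k list length per stratum (default 8).
#' @param ridge L2 penalty for [characteristic_direction()].
#' @param kind feature kind analyzed, default `"mirna"`.
#' @param min_lists minimum number of usable strata whose top-`k` must
#'   contain a feature; `NULL` (default) requires all usable strata.
#' @param balanced passed to [characteristic_direction()].
#' @param seed recorded in provenance (the selection itself is
#'   deterministic).
#' @return An object of class `consensus_report`; see
#'   [summary.consensus_report()], [as.data.frame.consensus_report()].
#' @export
run_consensus <- function(b, k = 8L, ridge = 1, kind = "mirna",
                          min_lists = NULL, balanced = FALSE, seed = NULL) {
  stopifnot(inherits(b, "cohort_bundle"))
  stc <- b$clinical$sample_type_code
  n_nonprimary <- sum(is.na(stc) | stc != "01")
  if (n_nonprimary > 0) b <- filter_primary(b)
  keep <- feature_kind(b$expression) == kind
  if (!any(keep)) stop("bundle has no '", kind, "' features", call. = FALSE)
  b$expression <- b$expression[keep, ]

  strata <- withCallingHandlers(build_strata(b),
                                warning = function(w) invokeRestart("muffleWarning"))
  usable <- attr(strata, "usable")
  if (!any(usable))
    stop("no usable stratum: every stratum lacks 2 samples in some cohort",
         call. = FALSE)
  used <- names(usable)[usable]
  if (is.null(min_lists)) min_lists <- length(used)
  if (min_lists < 1L || min_lists > length(used))
    stop("`min_lists` must lie in 1..", length(used), call. = FALSE)

  cohorts <- sort(unique(b$clinical$cohort))
  lists <- lapply(used, function(nm) {
    sub <- strata[[nm]]
    d <- characteristic_direction(sub$expression,
                                  factor(sub$clinical$cohort, levels = cohorts),
                                  ridge = ridge, balanced = balanced)
    top_k(d, k = min(k, nrow(sub$expression)), stratum_id = nm)
  })
  names(lists) <- used

  hits <- table(unlist(lapply(lists, `[[`, "feature_id")))
  selected <- sort(names(hits)[hits >= min_lists])

  per_stratum_rank <- NULL
  anova <- list()
  if (length(selected) > 0) {
    per_stratum_rank <- sapply(lists, function(l)
      l$rank[match(selected, l$feature_id)])
    per_stratum_rank <- matrix(per_stratum_rank, nrow = length(selected),
                               dimnames = list(selected, used))
    all_primary <- strata[["all_primary"]]
    ref <- if (!is.null(all_primary) && usable[["all_primary"]]) all_primary else b
    lab <- factor(ref$clinical$cohort, levels = cohorts)
    anova <- lapply(selected, function(f)
      anova_two_group(unclass(ref$expression)[f, ], lab))
    names(anova) <- selected
    # order markers by mean rank across usable strata
    ord <- order(rowMeans(per_stratum_rank, na.rm = TRUE), selected)
    selected <- selected[ord]
    per_stratum_rank <- per_stratum_rank[ord, , drop = FALSE]
    anova <- anova[selected]
  }

  structure(list(
    selected = selected,
    per_stratum_rank = per_stratum_rank,
    anova = anova,
    lists = lists,
    k = as.integer(k),
    min_lists = as.integer(min_lists),
    strata_used = used,
    strata_unusable = names(usable)[!usable],
    cohorts = cohorts,
    provenance = list(ridge = ridge, kind = kind, balanced = balanced,
                      seed = seed, n_nonprimary_removed = n_nonprimary,
                      n_samples = ncol(b$expression),
                      n_features = nrow(b$expression),
                      model = "L2-regularized multivariate logistic regression",
                      anova_stratum = "all_primary")
  ), class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf(
    "<consensus_report> %d markers in the top-%d of %d/%d strata (%s vs %s)\n",
    length(x$selected), x$k, x$min_lists,
    length(x$strata_used), x$cohorts[1L], x$cohorts[2L]))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  if (length(x$strata_unusable))
    cat("  unusable strata:", paste(x$strata_unusable, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate a consensus report
#'
#' One row per selected marker: per-cohort mean +/- sd on the pooled
#' primary stratum, ANOVA F and raw p, BH-adjusted p, and the rank the
#' marker attained in each stratum.
#'
#' @param x a `consensus_report`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame, one row per selected marker.
#' @export
as.data.frame.consensus_report <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  if (length(x$selected) == 0)
    return(data.frame(feature = character(0)))
  a <- x$anova
  g <- x$cohorts
  df <- data.frame(
    feature = x$selected,
    mean_1 = vapply(a, function(z) z$group_means[[g[1L]]], 0),
    sd_1 = vapply(a, function(z) z$group_sds[[g[1L]]], 0),
    mean_2 = vapply(a, function(z) z$group_means[[g[2L]]], 0),
    sd_2 = vapply(a, function(z) z$group_sds[[g[2L]]], 0),
    F = vapply(a, `[[`, 0, "F"),
    p = vapply(a, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  names(df)[2:5] <- c(paste0(g[1L], c("_mean", "_sd")),
                      paste0(g[2L], c("_mean", "_sd")))
  df$p_adj <- stats::p.adjust(df$p, method = "BH")
  rk <- as.data.frame(x$per_stratum_rank)
  names(rk) <- paste0("rank_", names(rk))
  rownames(df) <- NULL
  cbind(df, rk)
}

#' @export
summary.consensus_report <- function(object, ...) {
  cat(sprintf("Consensus markers (top-%d in %d of %d usable strata)\n",
              object$k, object$min_lists, length(object$strata_used)))
  cat("Strata:", paste(object$strata_used, collapse = ", "), "\n")
  if (length(object$strata_unusable))
    cat("Unusable:", paste(object$strata_unusable, collapse = ", "), "\n\n")
  if (length(object$selected) == 0) {
    cat("No marker reached consensus.\n")
    return(invisible(object))
  }
  df <- as.data.frame(object)
  g <- object$cohorts
  show <- data.frame(
    miRNA = df$feature,
    A = sprintf("%.3g +/- %.2g", df[[2L]], df[[3L]]),
    B = sprintf("%.3g +/- %.2g", df[[4L]], df[[5L]]),
    ANOVA = vapply(df$p, function(p) sub("^= ", "p = ",
                                         sub("^< ", "p < ", format_pvalue(p))), ""),
    stringsAsFactors = FALSE)
  names(show)[2:3] <- paste0(g, " (mean +/- std)")
  print(show, row.names = FALSE)
  invisible(object)
}

#' Write the consensus table as TSV
#'
#' The marker table of [as.data.frame.consensus_report()] with a
#' `# provenance:` comment header recording parameters and strata.
#'
#' @param x a `consensus_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_tsv <- function(x, path) {
  stopifnot(inherits(x, "consensus_report"))
  prov <- c(x$provenance[c("ridge", "kind", "balanced")],
            list(k = x$k, min_lists = x$min_lists,
                 strata = paste(x$strata_used, collapse = ",")))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s",
                     paste(sprintf("%s=%s", names(prov), unlist(prov)),
                           collapse = " ")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Violin-style marker plot
#'
#' Per-marker distribution of expression in the two cohorts on the
#' pooled primary stratum, drawn as jittered points over boxes — the
#' static counterpart of the violin diagrams used to present the markers.
#'
#' @param x a `consensus_report`.
#' @param b the `cohort_bundle` the report was fit on.
#' @param features markers to show, default all selected.
#' @param ... passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.consensus_report <- function(x, b, features = x$selected, ...) {
  stopifnot(inherits(b, "cohort_bundle"))
  if (length(features) == 0) stop("no selected markers to plot", call. = FALSE)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(features)),
                       mar = c(2.5, 4, 2, 1))
  on.exit(graphics::par(old))
  lab <- factor(b$clinical$cohort, levels = x$cohorts)
  for (f in features) {
    v <- unclass(b$expression)[f, ]
    graphics::boxplot(v ~ lab, main = f, xlab = "",
                      ylab = "log2(RPM+1)", outline = FALSE, ...)
    graphics::points(jitter(as.integer(lab), amount = 0.12), v,
                     pch = 19, cex = 0.5,
                     col = grDevices::adjustcolor(as.integer(lab) + 1, 0.6))
  }
  invisible(x)
}
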