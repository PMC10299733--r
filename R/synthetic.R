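#' Table of planted marker profiles
#'
#' Per-feature Gaussian group profiles on the log2(RPM+1) scale: the mean
#' and standard deviation of the feature in the PANNET cohort and in the
#' PGL cohort. The six default rows are the published mean +/- sd values
#' of the consensus markers (four elevated in PANNET, the two miR-10b
#' strands elevated in PGL).
#'
#' @param feature_id marker name.
#' @param mean_a,sd_a PANNET-cohort mean and sd, log2(RPM+1).
#' @param mean_b,sd_b PGL-cohort mean and sd, log2(RPM+1).
#' @return data.frame of class `feature_profile`.
#' @export
feature_profile <- function(feature_id, mean_a, sd_a, mean_b, sd_b) {
  stopifnot(all(sd_a > 0), all(sd_b > 0))
  out <- data.frame(feature_id = as.character(feature_id),
                    mean_a = mean_a, sd_a = sd_a,
                    mean_b = mean_b, sd_b = sd_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("feature_profile", "data.frame")
  out
}

#' @rdname feature_profile
#' @details `marker_profiles_table1()` returns the six published marker
#'   profiles (per-cohort mean +/- sd, log2(RPM+1)) used to calibrate the
#'   default synthetic study.
#' @export
marker_profiles_table1 <- function() {
  feature_profile(
    feature_id = c("hsa-miR-141-3p", "hsa-miR-200c-3p", "hsa-miR-10b-5p",
                   "hsa-miR-192-5p", "hsa-miR-194-5p", "hsa-miR-10b-3p"),
    mean_a = c(10.7, 13.4, 13.4, 13.7, 12.4, 2.65),
    sd_a   = c(0.76, 0.80, 1.0,  0.6,  0.72, 0.96),
    mean_b = c(1.66, 4.33, 17.8, 8.78, 7.65, 6.17),
    sd_b   = c(0.87, 1.09, 0.50, 0.87, 0.86, 0.65)
  )
}

#' Synthetic two-cohort study configuration
#'
#' Describes a synthetic PANNET-vs-PGL study: cohort sizes, the number of
#' miRNA features, the planted marker profiles, one shared background
#' Gaussian for all non-planted (null) features, and exact per-cohort
#' covariate compositions. [default_config()] reproduces the published
#' study conditions: 7 PANNET vs 149 primary PGL samples, 294 miRNAs,
#' the six published marker profiles planted, PGL gender split 64 male /
#' 85 female, all PANNETs "white" and 6 of 7 "not hispanic or latino"
#' (one unclassified). Two extra non-primary PGL samples (sample-type
#' codes "06" and "11") are included so the primary-tumor filter is
#' exercised; the all-primary analysis set is exactly 7 vs 149.
#'
#' @param n_a,n_b PANNET and PGL primary-sample counts.
#' @param n_features total miRNA feature count (planted + background).
#' @param planted a [feature_profile()] table.
#' @param background_mean,background_sd the shared Gaussian for null
#'   features, identical in both cohorts, log2(RPM+1).
#' @param covariates per-cohort named lists of category counts for
#'   `gender`, `race`, `ethnicity`; counts must sum to the cohort size
#'   and the category name `"missing"` encodes `NA`.
#' @param n_extra_nonprimary number of additional cohort-B samples with
#'   non-"01" sample-type codes.
#' @param extra_codes sample-type codes cycled over the extra samples.
#' @param n_genes size of an optional all-background gene block (for
#'   morphing-view demonstrations); 0 disables it.
#' @param seed default RNG seed used by [generate_cohort()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_a, n_b, n_features, planted,
                             background_mean = 6, background_sd = 1.2,
                             covariates = NULL,
                             n_extra_nonprimary = 0,
                             extra_codes = c("06", "11"),
                             n_genes = 0, seed = 1L) {
  stopifnot(inherits(planted, "feature_profile"))
  if (n_features < nrow(planted))
    stop("n_features (", n_features, ") is smaller than the number of ",
         "planted profiles (", nrow(planted), ")", call. = FALSE)
  if (is.null(covariates))
    covariates <- list(
      A = list(gender = c(male = ceiling(n_a / 2), female = floor(n_a / 2)),
               race = c(white = n_a),
               ethnicity = c("not hispanic or latino" = n_a)),
      B = list(gender = c(male = ceiling(n_b / 2), female = floor(n_b / 2)),
               race = c(white = n_b),
               ethnicity = c("not hispanic or latino" = n_b)))
  for (coh in names(covariates)) {
    n_coh <- if (coh == "A") n_a else n_b
    for (cv in names(covariates[[coh]])) {
      cnt <- covariates[[coh]][[cv]]
      if (any(cnt < 0) || sum(cnt) != n_coh)
        stop(sprintf("covariate counts for %s/%s must be >= 0 and sum to %d",
                     coh, cv, n_coh), call. = FALSE)
    }
  }
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 n_features = as.integer(n_features), planted = planted,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 covariates = covariates,
                 n_extra_nonprimary = as.integer(n_extra_nonprimary),
                 extra_codes = extra_codes,
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_config <- function(seed = 1L, n_genes = 0) {
  synthetic_config(
    n_a = 7L, n_b = 149L, n_features = 294L,
    planted = marker_profiles_table1(),
    background_mean = 6, background_sd = 1.2,
    covariates = list(
      A = list(gender = c(male = 3, female = 4),
               race = c(white = 7),
               ethnicity = c("not hispanic or latino" = 6, missing = 1)),
      B = list(gender = c(male = 64, female = 85),
               race = c(white = 120, "black or african american" = 15,
                        asian = 8, missing = 6),
               ethnicity = c("not hispanic or latino" = 130,
                             "hispanic or latino" = 10, missing = 9))),
    n_extra_nonprimary = 2L, extra_codes = c("06", "11"),
    n_genes = n_genes, seed = seed)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d PANNET + %d PGL (+%d non-primary), %d miRNAs (%d planted)\n",
    x$n_a, x$n_b, x$n_extra_nonprimary, x$n_features, nrow(x$planted)))
  print.data.frame(x$planted, row.names = FALSE)
  invisible(x)
}

# expand exact category counts to a randomly ordered assignment vector
draw_categories <- function(counts, n) {
  vals <- rep(names(counts), times = counts)
  vals[vals == "missing"] <- NA_character_
  sample(vals, n)
}

#' Generate a synthetic two-cohort bundle
#'
#' Draws an expression matrix with independent Gaussian values on the
#' log2(RPM+1) scale: planted features use their cohort-specific profile,
#' background features share one distribution in both cohorts, and all
#' values are clipped at 0. Clinical covariates realize the exact
#' per-cohort compositions of the configuration in a seed-determined
#' random order. Cohort A is labelled `"PANNET"`, cohort B `"PGL"`.
#'
#' @param cfg a [synthetic_config()].
#' @param seed RNG seed; defaults to `cfg$seed`. The output is
#'   bit-identical for identical `(cfg, seed)`.
#' @return A `cohort_bundle`.
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n_extra <- cfg$n_extra_nonprimary
  n_tot <- cfg$n_a + cfg$n_b + n_extra
  planted <- cfg$planted
  n_bg <- cfg$n_features - nrow(planted)
  ids <- c(planted$feature_id,
           if (n_bg > 0) sprintf("hsa-miR-bg-%03d", seq_len(n_bg)))

  # per-feature, per-sample Gaussian parameters; extras follow cohort B
  mean_a <- c(planted$mean_a, rep(cfg$background_mean, n_bg))
  mean_b <- c(planted$mean_b, rep(cfg$background_mean, n_bg))
  sd_a <- c(planted$sd_a, rep(cfg$background_sd, n_bg))
  sd_b <- c(planted$sd_b, rep(cfg$background_sd, n_bg))
  n_blike <- cfg$n_b + n_extra
  mu <- cbind(matrix(mean_a, cfg$n_features, cfg$n_a),
              matrix(mean_b, cfg$n_features, n_blike))
  sg <- cbind(matrix(sd_a, cfg$n_features, cfg$n_a),
              matrix(sd_b, cfg$n_features, n_blike))
  vals <- matrix(stats::rnorm(length(mu), mean = mu, sd = sg),
                 nrow = cfg$n_features)
  vals <- pmax(vals, 0)

  barcode <- c(sprintf("SYN-PAN-%04d-01", seq_len(cfg$n_a)),
               sprintf("SYN-PGL-%04d-01", seq_len(cfg$n_b)),
               if (n_extra > 0)
                 sprintf("SYN-PGL-%04d-%s", cfg$n_b + seq_len(n_extra),
                         rep_len(cfg$extra_codes, n_extra)))
  dimnames(vals) <- list(ids, barcode)
  m <- expr_matrix(vals, kind = "mirna")

  if (cfg$n_genes > 0) {
    gvals <- matrix(stats::rnorm(cfg$n_genes * n_tot,
                                 mean = cfg$background_mean,
                                 sd = cfg$background_sd),
                    nrow = cfg$n_genes,
                    dimnames = list(sprintf("GENE-bg-%04d", seq_len(cfg$n_genes)),
                                    barcode))
    m <- bind_features(m, expr_matrix(pmax(gvals, 0), kind = "gene"))
  }

  cov_a <- lapply(cfg$covariates$A, draw_categories, n = cfg$n_a)
  cov_b <- lapply(cfg$covariates$B, draw_categories, n = cfg$n_b)
  # extra non-primary samples: covariates drawn from the B composition again
  cov_x <- if (n_extra > 0)
    lapply(cfg$covariates$B, function(cnt) draw_categories(cnt, cfg$n_b)[seq_len(n_extra)])
  else
    lapply(cfg$covariates$B, function(cnt) character(0))

  cl <- clinical_table(
    sample = barcode,
    cohort = c(rep("PANNET", cfg$n_a), rep("PGL", n_blike)),
    gender = c(cov_a$gender, cov_b$gender, cov_x$gender),
    race = c(cov_a$race, cov_b$race, cov_x$race),
    ethnicity = c(cov_a$ethnicity, cov_b$ethnicity, cov_x$ethnicity))
  merge_clinical(m, cl)
}

#' Randomly reassign cohort labels
#'
#' Permutes the cohort labels across samples while preserving the group
#' sizes; expression values and all other covariates are untouched. This
#' is the null model used to measure selection specificity.
#'
#' @param b a two-cohort `cohort_bundle`.
#' @param seed RNG seed; the permutation is deterministic given `seed`.
#' @return The bundle with permuted `cohort` labels.
#' @export
permute_labels <- function(b, seed) {
  stopifnot(inherits(b, "cohort_bundle"))
  if (length(unique(b$clinical$cohort)) < 2L)
    stop("label permutation needs two cohorts", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  b$clinical$cohort <- sample(b$clinical$cohort)
  b
}
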