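# Stratified consensus selection and ANOVA confirmation.

test_that("the five demographic strata partition as declared", {
  b <- filter_primary(generate_cohort(default_config(seed = 2)))
  strata <- build_strata(b)
  expect_named(strata, c("all_primary", "male", "female", "white",
                         "not_hispanic_or_latino"))
  expect_true(all(attr(strata, "usable")))
  for (s in strata) {
    expect_identical(sort(unique(s$clinical$cohort)), c("PANNET", "PGL"))
    # every stratum is a subset of all_primary
    expect_true(all(s$clinical$sample %in%
                      strata$all_primary$clinical$sample))
  }

  # male + female = all_primary minus gender-missing samples
  mf <- c(strata$male$clinical$sample, strata$female$clinical$sample)
  known <- strata$all_primary$clinical$sample[
    !is.na(strata$all_primary$clinical$gender)]
  expect_setequal(mf, known)

  # an all-male cohort leaves the female stratum unusable
  b2 <- toy_bundle(toy_expr(nf = 4, ns = 8),
                   cohort = rep(c("PANNET", "PGL"), each = 4),
                   gender = "male", race = "white",
                   ethnicity = "not hispanic or latino")
  expect_warning(s2 <- build_strata(b2), "unusable strata.*female")
  expect_false(attr(s2, "usable")[["female"]])
  expect_true(attr(s2, "usable")[["male"]])
})

test_that("two-group ANOVA agrees with a sums-of-squares oracle", {
  a <- anova_two_group(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(a$F, 13.5)
  expect_identical(c(a$df_between, a$df_within), c(1L, 4L))
  orc <- anova_f_oracle(c(1, 2, 3, 4, 5, 6), rep(c("A", "B"), each = 3))
  expect_equal(a$F, orc$F)
  expect_equal(a$group_means[["A"]], 2)
  expect_equal(a$group_sds[["B"]], 1)

  # degenerate inputs: zero variance everywhere
  deg <- anova_two_group(c(2, 2, 2, 2), c("A", "A", "B", "B"))
  expect_true(is.na(deg$F) && is.na(deg$p))
  expect_match(deg$note, "undefined")
  sep <- anova_two_group(c(2, 2, 5, 5), c("A", "A", "B", "B"))
  expect_identical(sep$F, Inf)
  expect_identical(sep$p, 0)

  expect_error(anova_two_group(1:4, c("A", "B", "B", "B")), ">= 2 samples")
  expect_error(anova_two_group(1:4, rep("A", 4)), "two groups")

  # F = t^2 and identical p against the pooled-variance t-test
  for (s in 1:25) {
    set.seed(s)
    n1 <- sample(3:10, 1)
    n2 <- sample(3:10, 1)
    v <- c(rnorm(n1, 0), rnorm(n2, runif(1, -2, 2)))
    g <- rep(c("A", "B"), c(n1, n2))
    a <- anova_two_group(v, g)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-12)
    expect_equal(a$p, tt$p.value, tolerance = 1e-12)
  }
})

test_that("identical stratum rankings make the consensus equal the top-k", {
  # all-male, all-white, all-not-hispanic cohorts: every usable stratum
  # contains exactly the same samples, the ranked lists coincide, and the
  # consensus is the shared top-k
  cfg <- synthetic_config(
    n_a = 6, n_b = 10, n_features = 10,
    planted = feature_profile("hsa-miR-141-3p", 10.7, 0.76, 1.66, 0.87),
    covariates = list(
      A = list(gender = c(male = 6), race = c(white = 6),
               ethnicity = c("not hispanic or latino" = 6)),
      B = list(gender = c(male = 10), race = c(white = 10),
               ethnicity = c("not hispanic or latino" = 10))),
    seed = 5)
  rep5 <- run_consensus(generate_cohort(cfg), k = 4)
  expect_setequal(rep5$strata_used,
                  c("all_primary", "male", "white", "not_hispanic_or_latino"))
  expect_identical(rep5$strata_unusable, "female")
  base_list <- rep5$lists$all_primary
  expect_setequal(rep5$selected, base_list$feature_id)
  expect_identical(length(rep5$selected), 4L)
})

test_that("the default synthetic study yields exactly the planted consensus", {
  b <- generate_cohort(default_config(seed = 1))
  rep1 <- run_consensus(b, k = 8)
  expect_setequal(rep1$selected, default_config()$planted$feature_id)

  # report consistency: every selected marker ranks <= k in every stratum
  expect_true(all(rep1$per_stratum_rank <= rep1$k))
  expect_true(all(rep1$selected %in% rep1$lists$male$feature_id))
  expect_lte(length(rep1$selected), rep1$k)

  # ANOVA surface: strong significance and correct group ordering
  df <- as.data.frame(rep1)
  expect_true(all(df$p < 1e-4))
  expect_true(all(df$p_adj >= df$p))
  up_pannet <- c("hsa-miR-141-3p", "hsa-miR-200c-3p", "hsa-miR-192-5p",
                 "hsa-miR-194-5p")
  expect_true(all(df$PANNET_mean[df$feature %in% up_pannet] >
                    df$PGL_mean[df$feature %in% up_pannet]))
  down_pannet <- c("hsa-miR-10b-5p", "hsa-miR-10b-3p")
  expect_true(all(df$PANNET_mean[df$feature %in% down_pannet] <
                    df$PGL_mean[df$feature %in% down_pannet]))

  # provenance records the primary filter and parameters
  expect_identical(rep1$provenance$n_nonprimary_removed, 2L)
  expect_identical(rep1$provenance$n_samples, 156L)

  # relaxing min_lists can only grow the selection
  rep_relaxed <- run_consensus(b, k = 8, min_lists = 3)
  expect_true(all(rep1$selected %in% rep_relaxed$selected))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_consensus_tsv(rep1, path)
  tab <- read.delim(path, comment.char = "#")
  expect_identical(nrow(tab), 6L)
  expect_match(readLines(path, n = 1), "provenance")
})

test_that("degenerate consensus inputs fail or degrade as declared", {
  # single cohort: nothing to contrast
  b <- generate_cohort(small_config(seed = 3))
  single <- subset_samples(b, b$clinical$sample[b$clinical$cohort == "PGL"])
  expect_error(run_consensus(single), "no usable stratum")

  # a cohort with < 2 samples in some strata degrades to the usable ones
  cfg <- synthetic_config(
    n_a = 4, n_b = 12, n_features = 8,
    planted = feature_profile("hsa-miR-141-3p", 10.7, 0.76, 1.66, 0.87),
    covariates = list(
      A = list(gender = c(male = 4),                     # no female PANNET
               race = c(white = 4),
               ethnicity = c("not hispanic or latino" = 4)),
      B = list(gender = c(male = 6, female = 6),
               race = c(white = 12),
               ethnicity = c("not hispanic or latino" = 12))),
    seed = 8)
  rep2 <- run_consensus(generate_cohort(cfg), k = 3)
  expect_true("female" %in% rep2$strata_unusable)
  expect_true("hsa-miR-141-3p" %in% rep2$selected)
})
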