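# Control-free percentile normalization and cross-dataset validation.

test_that("global percentiles follow the midrank (rank - 0.5)/N rule", {
  m <- toy_expr(values = matrix(c(1, 2, 3, 4), 2, 2))
  p <- percentile_normalize(m)
  expect_equal(sort(as.vector(unclass(p))), c(0.125, 0.375, 0.625, 0.875))

  # all-tied matrix maps to 0.5 everywhere
  p_tied <- percentile_normalize(toy_expr(values = matrix(7, 3, 3)))
  expect_true(all(unclass(p_tied) == 0.5))

  # range and exact mean under no ties
  m2 <- toy_expr(nf = 5, ns = 8, seed = 3)
  p2 <- percentile_normalize(m2)
  expect_true(all(unclass(p2) > 0 & unclass(p2) < 1))
  expect_equal(mean(unclass(p2)), 0.5)

  # raw ordering is preserved within the dataset
  o_raw <- order(as.vector(unclass(m2)))
  o_pct <- order(as.vector(unclass(p2)))
  expect_identical(o_raw, o_pct)

  expect_error(percentile_normalize(m2[, character(0)]), "empty")
  bad <- unclass(m2)
  bad[1, 1] <- NA
  expect_error(percentile_normalize(toy_expr(values = bad)), "curate")
})

test_that("percentiles match the exhaustive pairwise-comparison oracle", {
  # all shapes up to 3x3 with distinct values, plus tied variants
  for (nr in 1:3) for (nc in 1:3) {
    if (nr * nc < 2) next
    for (s in 1:5) {
      set.seed(100 * nr + 10 * nc + s)
      v <- matrix(sample(seq(-50, 50), nr * nc), nr, nc)
      m <- toy_expr(values = v)
      p <- percentile_normalize(m)
      expect_equal(as.vector(unclass(p)), percentile_oracle(v))
      # tied variant: duplicate one value
      if (nr * nc >= 3) {
        v2 <- v
        v2[1] <- v2[length(v2)]
        pt <- percentile_normalize(toy_expr(values = v2))
        expect_equal(as.vector(unclass(pt)), percentile_oracle(v2))
      }
    }
  }
})

test_that("per-feature pooling ranks within each row", {
  v <- matrix(c(1, 100, 2, 200, 3, 300), 2, 3)
  p <- percentile_normalize(toy_expr(values = v), pool = "per_feature")
  expect_equal(unname(unclass(p)[1, ]), c(1 - 0.5, 2 - 0.5, 3 - 0.5) / 3)
  expect_equal(unclass(p)[1, ], unclass(p)[2, ])
})

test_that("strictly increasing transforms leave percentiles unchanged", {
  m <- toy_expr(nf = 6, ns = 9, seed = 4)
  p <- percentile_normalize(m)
  for (f in list(function(x) 2 * x + 7, exp, function(x) x^3)) {
    mt <- toy_expr(values = f(unclass(m)))
    expect_equal(unclass(percentile_normalize(mt)), unclass(p))
  }
})

test_that("group comparison on percentiles detects shifts and nulls", {
  # identical distributions in both groups: p = 1, no direction
  v <- matrix(rep(1:6, 2), nrow = 1)
  m <- toy_expr(values = v)
  colnames(m) <- sprintf("S-%02d-01", 1:12)
  p <- percentile_normalize(m)
  cmp <- compare_groups(p, rep(c("A", "B"), each = 6))
  expect_gt(cmp$p, 0.99)
  expect_identical(cmp$direction, "none")

  # +2 pooled-sd shift at n = 48 vs 50: significant, agreeing with a
  # rank-sum oracle at alpha = 0.01
  set.seed(17)
  vals <- rbind(c(rnorm(48, 8), rnorm(50, 6)),
                matrix(rnorm(5 * 98, 6), 5, 98))
  m2 <- toy_expr(values = vals)
  lab <- rep(c("PGL", "PANNET"), c(48, 50))
  p2 <- percentile_normalize(m2)
  cmp2 <- compare_groups(p2, lab, features = rownames(m2)[1])
  expect_lt(cmp2$p, 0.01)
  # "up" means higher in the first-named group (PANNET here); the shift
  # favors PGL, so the direction is "down"
  expect_identical(cmp2$direction, "down")
  wilcox_p <- wilcox.test(unclass(p2)[1, lab == "PGL"],
                          unclass(p2)[1, lab == "PANNET"])$p.value
  expect_lt(wilcox_p, 0.01)
  cmp2r <- compare_groups(p2, lab, features = rownames(m2)[1],
                          test = "ranksum")
  expect_equal(cmp2r$p, wilcox_p)

  # absent features are reported, not fatal
  cmp3 <- compare_groups(p2, lab, features = c("hsa-miR-absent",
                                               rownames(m2)[1]))
  expect_true(cmp3$missing[1])
  expect_false(cmp3$missing[2])
})

test_that("cross-dataset validation is rank-invariant and direction-correct", {
  # emulated validation pair: one PANNET-only and one PGL-only dataset,
  # independently generated and independently normalized
  b <- generate_cohort(
    synthetic_config(n_a = 50, n_b = 48, n_features = 294,
                     planted = marker_profiles_table1(), seed = 23))
  pannet_only <- subset_samples(b, b$clinical$sample[b$clinical$cohort == "PANNET"])
  pgl_only <- subset_samples(b, b$clinical$sample[b$clinical$cohort == "PGL"])
  markers <- marker_profiles_table1()$feature_id

  rep1 <- cross_dataset_report(list(GSE_PANNET = pannet_only,
                                    GSE_PGL = pgl_only),
                               features = markers)
  agg <- rep1$per_dataset
  med <- function(f, ds) agg$median_percentile[agg$feature == f &
                                                 agg$dataset == ds]
  up_pannet <- c("hsa-miR-141-3p", "hsa-miR-200c-3p", "hsa-miR-192-5p",
                 "hsa-miR-194-5p")
  for (f in up_pannet) expect_gt(med(f, "GSE_PANNET"), med(f, "GSE_PGL"))
  for (f in c("hsa-miR-10b-5p", "hsa-miR-10b-3p"))
    expect_gt(med(f, "GSE_PGL"), med(f, "GSE_PANNET"))

  dirs <- setNames(rep1$comparison$direction, rep1$comparison$feature)
  expect_true(all(dirs[up_pannet] == "up"))          # up = higher in PANNET
  expect_true(all(rep1$comparison$p < 0.01))

  # two copies of one dataset under different ids normalize identically
  rep2 <- cross_dataset_report(list(a = pannet_only, b = pannet_only,
                                    c = pgl_only), features = markers)
  pa <- rep2$percentiles
  expect_identical(pa$percentile[pa$dataset == "a"],
                   pa$percentile[pa$dataset == "b"])

  # shifting one dataset's raw values leaves its percentiles unchanged
  shifted <- pgl_only
  shifted$expression <- expr_matrix(unclass(pgl_only$expression) + 11,
                                    kind = feature_kind(pgl_only$expression))
  rep3 <- cross_dataset_report(list(GSE_PANNET = pannet_only,
                                    GSE_PGL = shifted), features = markers)
  expect_equal(rep3$comparison$p, rep1$comparison$p)
  expect_identical(rep3$comparison$direction, rep1$comparison$direction)

  expect_error(cross_dataset_report(list(only = pannet_only),
                                    features = markers), "at least 2")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_validation_tsv(rep1, path)
  tab <- read.delim(path)
  expect_identical(sort(unique(tab$feature)), sort(markers))
})
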