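# Small fixtures and independent oracles, built in code.

toy_expr <- function(values = NULL, nf = 3, ns = 2, kind = "mirna", seed = 1) {
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(round(stats::rnorm(nf * ns, 6, 1), 3), nf, ns)
  }
  dimnames(values) <- list(sprintf("hsa-miR-t%02d", seq_len(nrow(values))),
                           sprintf("TOY-%04d-01", seq_len(ncol(values))))
  expr_matrix(values, kind = kind)
}

toy_bundle <- function(m, cohort, gender = NA, race = NA, ethnicity = NA) {
  merge_clinical(m, clinical_table(sample = colnames(m), cohort = cohort,
                                   gender = gender, race = race,
                                   ethnicity = ethnicity))
}

# a reduced-size synthetic study for fast property checks
small_config <- function(n_a = 10, n_b = 20, n_features = 30, seed = 1, ...) {
  synthetic_config(
    n_a = n_a, n_b = n_b, n_features = n_features,
    planted = feature_profile("hsa-miR-141-3p", 10.7, 0.76, 1.66, 0.87),
    covariates = list(
      A = list(gender = c(male = ceiling(n_a / 2), female = floor(n_a / 2)),
               race = c(white = n_a),
               ethnicity = c("not hispanic or latino" = n_a)),
      B = list(gender = c(male = ceiling(n_b / 2), female = floor(n_b / 2)),
               race = c(white = n_b),
               ethnicity = c("not hispanic or latino" = n_b))),
    seed = seed, ...)
}

# one-way ANOVA F from first-principles sums of squares
anova_f_oracle <- function(values, labels) {
  labels <- as.factor(labels)
  grand <- mean(values)
  ssb <- sum(tapply(values, labels, function(g) length(g) * (mean(g) - grand)^2))
  ssw <- sum(tapply(values, labels, function(g) sum((g - mean(g))^2)))
  dfb <- nlevels(labels) - 1L
  dfw <- length(values) - nlevels(labels)
  list(F = (ssb / dfb) / (ssw / dfw), df_between = dfb, df_within = dfw)
}

# mean silhouette width computed directly from Euclidean distances
direct_silhouette <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  labels <- as.character(labels)
  s <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# exhaustive percentile oracle: percentile of every cell from pairwise
# comparisons only ((#smaller + (#equal)/2) / N maps to the midrank rule)
percentile_oracle <- function(v) {
  cells <- as.vector(v)
  vapply(cells, function(x)
    (sum(cells < x) + (sum(cells == x) + 1) / 2 - 0.5) / length(cells), 0)
}

# numeric content of an expr_matrix, ignoring bookkeeping attributes
strip_attrs <- function(m) {
  x <- unclass(m)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

rotate2d <- function(coords, degrees) {
  th <- degrees * pi / 180
  coords %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

expect_unit_norm <- function(d, tol = 1e-9) {
  expect_equal(sum(coef(d)^2), 1, tolerance = tol)
}
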