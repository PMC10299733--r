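#' Standardize features to zero mean and unit variance
#'
#' Centers every feature (row) to mean 0 and scales it to standard
#' deviation 1 across samples, so that logistic-regression coefficients
#' are comparable between features. Zero-variance features are centered
#' only (all zeros) and recorded in the `"constant_features"` attribute.
#' The operation is idempotent.
#'
#' @param m an [expr_matrix()] with at least 2 samples.
#' @return The standardized `expr_matrix`.
#' @export
standardize_features <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m) < 2L) stop("standardization needs >= 2 samples", call. = FALSE)
  v <- unclass(m)
  mu <- rowMeans(v)
  s <- apply(v, 1L, stats::sd)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  out <- expr_matrix((v - mu) / s, kind = feature_kind(m))
  attr(out, "constant_features") <- rownames(m)[const]
  out
}

# penalized negative log-likelihood, glmnet scaling:
#   f(b0, b) = -(1/n) sum_i w_i [y_i eta_i - log(1 + exp(eta_i))] + (ridge/2)||b||^2
ridge_logistic_objective <- function(beta0, beta, x, y, ridge, w) {
  eta <- beta0 + drop(x %*% beta)
  # overflow-safe log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
  log1pe <- pmax(eta, 0) + log1p(exp(-abs(eta)))
  -mean(w * (y * eta - log1pe)) + ridge / 2 * sum(beta^2)
}

# damped Newton fit of the objective above; intercept unpenalized
ridge_logistic_fit <- function(x, y, ridge, w = rep(1, length(y)),
                               max_iter = 200L, tol = 1e-12) {
  n <- nrow(x)
  p <- ncol(x)
  z <- cbind(1, x)
  pen <- c(0, rep(ridge, p))
  beta <- numeric(p + 1L)
  obj <- ridge_logistic_objective(beta[1L], beta[-1L], x, y, ridge, w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(z %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(z, w * (mu - y))) / n + pen * beta
    wt <- pmax(w * mu * (1 - mu), 1e-10)
    hess <- crossprod(z * wt, z) / n + diag(pen, p + 1L)
    step <- solve(hess, grad)
    # step halving keeps the iteration monotone when curvature is low
    lam <- 1
    repeat {
      cand <- beta - lam * step
      cand_obj <- ridge_logistic_objective(cand[1L], cand[-1L], x, y, ridge, w)
      if (is.finite(cand_obj) && cand_obj <= obj + 1e-14) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    delta <- obj - cand_obj
    beta <- cand
    obj <- cand_obj
    if (max(abs(grad)) < tol || (delta >= 0 && delta < tol)) {
      converged <- TRUE
      break
    }
  }
  if (!all(is.finite(beta)))
    stop("ridge logistic fit diverged; increase `ridge`", call. = FALSE)
  list(intercept = beta[1L], coefficients = beta[-1L], converged = converged,
       objective = obj, iterations = it)
}

#' Characteristic-direction ranking vector
#'
#' Estimates the multivariate discriminative direction separating two
#' sample groups in expression space: the coefficient vector of an
#' L2-regularized logistic regression of group membership on all
#' (standardized) features jointly, normalized to unit Euclidean length.
#' Features whose coefficients have large magnitude contribute most to
#' the separation between the groups; the per-feature ranking is obtained
#' with [top_k()]. The ridge penalty keeps the fit well-posed when
#' features outnumber samples and under complete separation, both the
#' norm for small-cohort miRNA comparisons.
#'
#' Orientation: a positive coefficient means the feature is elevated in
#' the first level of `labels`.
#'
#' @param m an [expr_matrix()]; features are standardized internally
#'   (idempotent, so pre-standardized input is unchanged).
#' @param labels two-group factor (or coercible) over the samples of `m`;
#'   the first level is the positive class.
#' @param ridge L2 penalty strength (on the glmnet `lambda` scale),
#'   default 1.
#' @param balanced use inverse-frequency class weights? Default `FALSE`:
#'   group imbalance is addressed by stratified re-analysis rather than
#'   re-weighting.
#' @param max_iter,tol Newton iteration controls.
#' @return An object of class `char_direction`: `feature_ids`,
#'   `coefficients` (unit norm), `intercept` and `scale` (the raw-fit
#'   intercept and coefficient norm), `groups`, `ridge`.
#' @export
characteristic_direction <- function(m, labels, ridge = 1, balanced = FALSE,
                                     max_iter = 200L, tol = 1e-12) {
  stopifnot(inherits(m, "expr_matrix"))
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(labels) != ncol(m))
    stop("`labels` must give one group per sample", call. = FALSE)
  if (nlevels(labels) != 2L)
    stop("exactly two groups required, got ", nlevels(labels), call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("each group needs >= 2 samples (smallest has ", min(sizes), ")",
         call. = FALSE)
  if (!is.numeric(ridge) || ridge <= 0)
    stop("`ridge` must be a positive penalty strength", call. = FALSE)
  ms <- standardize_features(m)
  x <- t(unclass(ms))
  y <- as.numeric(labels == levels(labels)[1L])
  w <- if (balanced) {
    cw <- length(y) / (2 * c(sum(y == 0), sum(y == 1)))
    cw[y + 1]
  } else rep(1, length(y))
  fit <- ridge_logistic_fit(x, y, ridge = ridge, w = w,
                            max_iter = max_iter, tol = tol)
  b <- fit$coefficients
  if (!all(is.finite(b)))
    stop("non-finite coefficients; increase `ridge`", call. = FALSE)
  nrm <- sqrt(sum(b^2))
  if (nrm == 0) nrm <- 1
  structure(list(feature_ids = rownames(m),
                 coefficients = stats::setNames(b / nrm, rownames(m)),
                 intercept = fit$intercept, scale = nrm,
                 groups = levels(labels),
                 ridge = ridge, balanced = balanced,
                 converged = fit$converged,
                 constant_features = attr(ms, "constant_features"),
                 model = "L2-regularized multivariate logistic regression"),
            class = "char_direction")
}

#' @export
print.char_direction <- function(x, ...) {
  cat(sprintf("<char_direction> %s vs %s, %d features, ridge = %g\n",
              x$groups[1L], x$groups[2L], length(x$coefficients), x$ridge))
  cat("  orientation: positive coefficient => elevated in", x$groups[1L], "\n")
  top <- utils::head(top_k(x, min(5L, length(x$coefficients))), 5L)
  cat("  leading features:",
      paste(sprintf("%s (%.3f)", top$feature_id,
                    top$score * top$sign), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.char_direction <- function(object, ...) object$coefficients

#' Predict group membership from a characteristic direction
#'
#' Logistic probabilities of the positive class (the first-named group)
#' for new samples, using the unnormalized fitted coefficients.
#'
#' @param object a `char_direction`.
#' @param newdata an `expr_matrix` over the same features (standardized
#'   internally).
#' @param type `"response"` for probabilities, `"class"` for labels.
#' @param ... unused.
#' @return numeric vector of probabilities or character vector of labels.
#' @export
predict.char_direction <- function(object, newdata,
                                   type = c("response", "class"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "expr_matrix"))
  if (!identical(rownames(newdata), object$feature_ids))
    newdata <- newdata[object$feature_ids, ]
  x <- t(unclass(standardize_features(newdata)))
  eta <- object$intercept + drop(x %*% (object$coefficients * object$scale))
  p <- stats::plogis(eta)
  if (type == "response") return(stats::setNames(p, colnames(newdata)))
  stats::setNames(ifelse(p >= 0.5, object$groups[1L], object$groups[2L]),
                  colnames(newdata))
}

#' Top-k ranked feature list
#'
#' Orders all features by decreasing coefficient magnitude (ties broken
#' lexicographically by feature id, so the ranking is deterministic) and
#' returns the leading `k`.
#'
#' @param d a [characteristic_direction()] fit.
#' @param k number of entries, `1 <= k <=` feature count. The published
#'   analysis used the top eight positions of each list.
#' @param stratum_id optional label recorded with the list.
#' @return A `data.frame` of class `ranked_list` with columns `rank`,
#'   `feature_id`, `score` (`|coefficient|`), `sign`.
#' @export
top_k <- function(d, k = 8L, stratum_id = NA_character_) {
  stopifnot(inherits(d, "char_direction"))
  p <- length(d$coefficients)
  if (!is.numeric(k) || k < 1L || k > p)
    stop("`k` must lie in 1..", p, ", got ", k, call. = FALSE)
  score <- abs(d$coefficients)
  ord <- order(-score, d$feature_ids)
  ord <- ord[seq_len(as.integer(k))]
  out <- data.frame(rank = seq_len(as.integer(k)),
                    feature_id = d$feature_ids[ord],
                    score = unname(score[ord]),
                    sign = unname(sign(d$coefficients[ord])),
                    stringsAsFactors = FALSE)
  attr(out, "stratum_id") <- stratum_id
  attr(out, "groups") <- d$groups
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Export a ranked list as TSV
#'
#' Columns `stratum`, `rank`, `feature_id`, `score`, `sign`.
#'
#' @param rl a [top_k()] result (or list of them).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list_tsv <- function(rl, path) {
  if (inherits(rl, "ranked_list")) rl <- list(rl)
  rows <- do.call(rbind, lapply(rl, function(r)
    cbind(stratum = attr(r, "stratum_id"), as.data.frame(r))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
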