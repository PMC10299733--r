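#' t-SNE embedding of one feature view
#'
#' Projects the samples of a bundle to 2D with t-distributed stochastic
#' neighbor embedding, using only the features of the requested kind
#' (the "gene view" or the "miRNA view" of the same samples). Distances
#' are Euclidean on the log2 expression values (optionally standardized
#' per feature). The perplexity is lowered automatically to
#' `floor((n - 1) / 3)` when the sample count cannot support the request,
#' so small cohorts embed without manual tuning. Coordinates are centered
#' at the origin and deterministic for a fixed seed.
#'
#' @param b a `cohort_bundle`.
#' @param view feature kind to embed, `"mirna"` or `"gene"`.
#' @param perplexity t-SNE perplexity; must end up below `(n - 1) / 3`.
#' @param seed RNG seed (mandatory; t-SNE is stochastic).
#' @param standardize standardize features to unit variance first?
#' @param max_iter gradient-descent iterations.
#' @return An object of class `tsne_embedding`: list with `sample_ids`,
#'   `coords` (n x 2), `view_label` and `params`.
#' @export
embed_tsne <- function(b, view = c("mirna", "gene"), perplexity = 30,
                       seed, standardize = FALSE, max_iter = 1000) {
  stopifnot(inherits(b, "cohort_bundle"))
  if (missing(seed)) stop("`seed` is required: t-SNE is stochastic",
                          call. = FALSE)
  view <- match.arg(view)
  keep <- feature_kind(b$expression) == view
  if (!any(keep)) stop("bundle has no '", view, "' features", call. = FALSE)
  x <- t(unclass(b$expression)[keep, , drop = FALSE])
  n <- nrow(x)
  if (n < 4L) stop("t-SNE needs at least 4 samples, got ", n, call. = FALSE)
  max_perp <- floor((n - 1) / 3)
  perplexity <- min(perplexity, max_perp)
  if (perplexity < 1)
    stop(sprintf("perplexity must satisfy perplexity <= floor((n-1)/3) = %d",
                 max_perp), call. = FALSE)
  if (standardize) {
    s <- apply(x, 2L, stats::sd)
    s[s == 0] <- 1
    x <- scale(x, scale = s)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2L, perplexity = perplexity,
                      max_iter = max_iter, check_duplicates = FALSE,
                      pca = FALSE, verbose = FALSE)
  coords <- sweep(fit$Y, 2L, colMeans(fit$Y))
  rownames(coords) <- rownames(x)
  structure(list(sample_ids = rownames(x), coords = coords,
                 view_label = view,
                 params = list(perplexity = perplexity, seed = seed,
                               max_iter = max_iter,
                               standardize = standardize)),
            class = "tsne_embedding")
}

#' Construct an embedding from raw coordinates
#'
#' Wraps precomputed 2D coordinates (from any projection method) in the
#' container used by the alignment and morphing stages.
#'
#' @param coords n x 2 numeric matrix.
#' @param sample_ids sample barcodes, one per row.
#' @param view_label label for the feature view.
#' @return A `tsne_embedding`.
#' @export
as_embedding <- function(coords, sample_ids = rownames(coords),
                         view_label = "custom") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2L, all(is.finite(coords)),
            length(sample_ids) == nrow(coords))
  rownames(coords) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids), coords = coords,
                 view_label = view_label, params = list()),
            class = "tsne_embedding")
}

#' @export
print.tsne_embedding <- function(x, ...) {
  cat(sprintf("<tsne_embedding> view '%s', %d samples\n",
              x$view_label, length(x$sample_ids)))
  invisible(x)
}

#' @export
plot.tsne_embedding <- function(x, col = 1, pch = 19, ...) {
  graphics::plot(x$coords, col = col, pch = pch, asp = 1,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = paste0(x$view_label, " view"), ...)
  invisible(x)
}

#' Rigidly align one embedding onto another
#'
#' Orthogonal Procrustes alignment: finds the rotation/reflection,
#' isotropic scale and translation of `b` minimizing the summed squared
#' distance to `a`, via the closed-form SVD solution. Independently run
#' t-SNE maps differ by an arbitrary rigid transform, so alignment is a
#' precondition for meaningful morphing between views. `a` is never
#' modified.
#'
#' @param a reference `tsne_embedding`.
#' @param b `tsne_embedding` to transform; identical sample ids and order
#'   as `a`.
#' @return `b` with transformed coordinates; the transform and residual
#'   sum of squares are attached as attribute `"procrustes"`.
#' @export
align_embeddings <- function(a, b) {
  stopifnot(inherits(a, "tsne_embedding"), inherits(b, "tsne_embedding"))
  if (!identical(a$sample_ids, b$sample_ids))
    stop("embeddings cover different samples (ids or order differ)",
         call. = FALSE)
  A <- a$coords
  B <- b$coords
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca)
  Bc <- sweep(B, 2L, cb)
  sv <- svd(crossprod(Bc, Ac))
  rot <- sv$u %*% t(sv$v)            # reflections permitted
  s <- sum(sv$d) / sum(Bc^2)
  new_coords <- s * (Bc %*% rot) + rep(ca, each = nrow(A))
  rownames(new_coords) <- rownames(B)
  out <- b
  out$coords <- new_coords
  attr(out, "procrustes") <- list(rotation = rot, scale = s,
                                  translation = ca - s * (cb %*% rot),
                                  rss = sum((A - new_coords)^2))
  out
}

#' Convex blend of two aligned embeddings
#'
#' One morph frame at weight `w`: per-sample coordinates
#' `(1 - w) * a + w * b_aligned`. At `w = 0` the frame equals view `a`
#' exactly; at `w = 1` it equals the aligned view `b`.
#'
#' @param a reference `tsne_embedding`.
#' @param b_aligned `tsne_embedding` already aligned to `a` (see
#'   [align_embeddings()]).
#' @param w blend weight in `[0, 1]`.
#' @return An object of class `morph_frame`: list with `coords`,
#'   `weight`, `sample_ids`.
#' @export
morph <- function(a, b_aligned, w) {
  stopifnot(inherits(a, "tsne_embedding"), inherits(b_aligned, "tsne_embedding"))
  if (!identical(a$sample_ids, b_aligned$sample_ids))
    stop("embeddings cover different samples (ids or order differ)",
         call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("blend weight must lie in [0, 1], got ", w, call. = FALSE)
  structure(list(coords = (1 - w) * a$coords + w * b_aligned$coords,
                 weight = w, sample_ids = a$sample_ids),
            class = "morph_frame")
}

#' @export
print.morph_frame <- function(x, ...) {
  cat(sprintf("<morph_frame> w = %.3f, %d samples\n",
              x$weight, length(x$sample_ids)))
  invisible(x)
}

#' Sequence of morph frames between two views
#'
#' Frames at weights evenly spaced on `[0, 1]`; the first frame equals
#' the reference view, the last equals the aligned target view. Each
#' sample travels a straight line, so consecutive frames differ by at
#' most `1 / (n_frames - 1)` of its endpoint displacement — the smooth
#' animated transition between feature views.
#'
#' @inheritParams morph
#' @param n_frames number of frames, at least 2.
#' @return list of `morph_frame` objects, class `morph_sequence`.
#' @export
frame_sequence <- function(a, b_aligned, n_frames) {
  if (!is.numeric(n_frames) || n_frames < 2L)
    stop("n_frames must be an integer >= 2", call. = FALSE)
  w <- seq(0, 1, length.out = as.integer(n_frames))
  structure(lapply(w, function(wi) morph(a, b_aligned, wi)),
            class = "morph_sequence")
}

#' @export
print.morph_sequence <- function(x, ...) {
  cat(sprintf("<morph_sequence> %d frames, %d samples\n",
              length(x), length(x[[1L]]$sample_ids)))
  invisible(x)
}

#' Export morph frames as TSV
#'
#' Long-format table with columns `sample_id`, `x`, `y`, `weight`.
#'
#' @param frames a `morph_sequence` (or list of `morph_frame`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(frames, path) {
  rows <- do.call(rbind, lapply(frames, function(f)
    data.frame(sample_id = f$sample_ids, x = f$coords[, 1L],
               y = f$coords[, 2L], weight = f$weight,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
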