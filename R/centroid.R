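#' Nearest-centroid base classifier
#'
#' The base learner of the cascade. Fitting computes, for each feature of
#' one feature set, the class-wise mean over the training samples, giving a
#' positive and a negative centroid vector. A sample's score is the signed
#' difference of its distances to the two centroids,
#' `d(x, centroid_neg) - d(x, centroid_pos)`, so a positive score means the
#' sample lies nearer the positive centroid. No shrinkage is applied.
#'
#' The distance is Euclidean by default (the canonical choice for
#' nearest-centroid classification of z-scored data); a correlation distance
#' `1 - cor(x, centroid)` is available as a non-default option.
#'
#' @param x_sub numeric matrix restricted to one feature set
#'   (samples in rows).
#' @param y 0/1 labels, one per row of `x_sub`; both classes must be
#'   present.
#' @param distance `"euclidean"` (default) or `"correlation"`.
#' @return An object of class `"centroid_model"` with fields
#'   `centroid_pos`, `centroid_neg`, `distance` and `n_features`.
#' @examples
#' x <- rbind(c(0, 0), c(2, 2), c(4, 4))
#' fit <- fit_centroid(x, c(1, 1, 0))
#' fit$centroid_pos  # (1, 1)
#' score_centroid(fit, x)
#' @export
fit_centroid <- function(x_sub, y, distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  x_sub <- check_matrix(x_sub, "x_sub")
  y <- as.integer(y)
  if (length(y) != nrow(x_sub)) stop_dc("label length != sample count")
  if (!any(y == 1L) || !any(y == 0L))
    stop_dc("fit_centroid needs at least one sample per class")
  cp <- colMeans(x_sub[y == 1L, , drop = FALSE])
  cn <- colMeans(x_sub[y == 0L, , drop = FALSE])
  if (!all(is.finite(cp)) || !all(is.finite(cn)))
    stop_dc("non-finite centroid; check the input matrix")
  structure(list(centroid_pos = cp, centroid_neg = cn,
                 distance = distance, n_features = ncol(x_sub)),
            class = "centroid_model")
}

dist_to <- function(x_sub, centroid, distance) {
  if (distance == "euclidean") {
    ## d^2 = |x|^2 - 2 x.c + |c|^2, computed via BLAS for speed
    d2 <- rowSums(x_sub^2) - 2 * drop(x_sub %*% centroid) +
      sum(centroid^2)
    sqrt(pmax(d2, 0))
  } else {
    sx <- x_sub - rowMeans(x_sub)
    sc <- centroid - mean(centroid)
    den <- sqrt(rowSums(sx^2) * sum(sc^2))
    r <- ifelse(den > 0, drop(sx %*% sc) / den, 0)
    1 - r
  }
}

# Validation-free fitting used on the cascade's hot path; the resampler
# guarantees both classes are present.
fit_centroid_fast <- function(x_sub, y, distance = "euclidean") {
  structure(list(centroid_pos = colMeans(x_sub[y == 1L, , drop = FALSE]),
                 centroid_neg = colMeans(x_sub[y == 0L, , drop = FALSE]),
                 distance = distance, n_features = ncol(x_sub)),
            class = "centroid_model")
}

# Validation-free scoring used on the cascade's hot path.
score_centroid_fast <- function(model, x_sub) {
  if (model$distance == "euclidean") {
    cc <- cbind(model$centroid_neg, model$centroid_pos)
    xp <- x_sub %*% cc
    r2 <- rowSums(x_sub * x_sub)
    sqrt(pmax(r2 - 2 * xp[, 1L] + sum(cc[, 1L]^2), 0)) -
      sqrt(pmax(r2 - 2 * xp[, 2L] + sum(cc[, 2L]^2), 0))
  } else {
    dist_to(x_sub, model$centroid_neg, model$distance) -
      dist_to(x_sub, model$centroid_pos, model$distance)
  }
}

#' Score samples against a fitted centroid model
#'
#' @param model a `centroid_model` from [fit_centroid()].
#' @param x_sub matrix with the same columns (feature set) the model was
#'   fitted on.
#' @return One signed score per sample: positive when the sample is nearer
#'   the positive centroid, zero when equidistant.
#' @export
score_centroid <- function(model, x_sub) {
  stopifnot(inherits(model, "centroid_model"))
  x_sub <- check_matrix(x_sub, "x_sub")
  if (ncol(x_sub) != model$n_features)
    stop_dc("x_sub has %d columns, model expects %d",
            ncol(x_sub), model$n_features)
  score_centroid_fast(x_sub = x_sub, model = model)
}

#' Predict hard labels from a centroid model
#'
#' A sample is labelled positive iff its signed score is strictly greater
#' than zero; exact ties (equidistant samples) are labelled negative, a
#' deterministic and conservative convention for case/control screening.
#'
#' @inheritParams score_centroid
#' @return Integer 0/1 labels.
#' @export
predict_centroid <- function(model, x_sub) {
  as.integer(score_centroid(model, x_sub) > 0)
}

#' The pluggable base-classifier contract
#'
#' Cascade layers are agnostic to the base learner: any object created by
#' `base_classifier()` can stand in for the nearest-centroid default. The
#' contract is a pair of functions:
#' \describe{
#'   \item{fit(x_sub, y)}{returns an opaque state from a sub-matrix and 0/1
#'     labels (both classes present).}
#'   \item{score(state, x_sub)}{returns one finite real score per sample,
#'     higher meaning more positive; a hard label is `score > 0`.}
#' }
#'
#' @param fit,score functions implementing the contract.
#' @param name identifier used in printouts.
#' @return An object of class `"base_classifier"`.
#' @examples
#' # the built-in default
#' ncc <- ncc_classifier()
#' st <- ncc$fit(matrix(rnorm(20), 10), rep(0:1, 5))
#' ncc$score(st, matrix(rnorm(4), 2))
#' @export
base_classifier <- function(fit, score, name = "custom") {
  stopifnot(is.function(fit), is.function(score))
  structure(list(fit = fit, score = score, name = name),
            class = "base_classifier")
}

#' @rdname base_classifier
#' @param distance distance metric passed to [fit_centroid()].
#' @export
ncc_classifier <- function(distance = "euclidean") {
  base_classifier(
    fit = function(x_sub, y) fit_centroid_fast(x_sub, y, distance = distance),
    score = function(state, x_sub) score_centroid_fast(state, x_sub),
    name = paste0("nearest_centroid(", distance, ")"))
}

resolve_base_classifier <- function(base) {
  if (inherits(base, "base_classifier")) return(base)
  if (is.character(base) && base %in% c("nearest_centroid", "ncc"))
    return(ncc_classifier())
  stop_dc("unknown base classifier; pass \"nearest_centroid\" or a base_classifier() object")
}
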