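align_features <- function(x, needed, what = "newdata") {
  if (!is.null(colnames(x))) {
    missing <- setdiff(needed, colnames(x))
    if (length(missing))
      stop_dc("%s lacks %d required feature(s): %s%s", what, length(missing),
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ..." else "")
    x[, needed, drop = FALSE]
  } else {
    if (ncol(x) != length(needed))
      stop_dc("%s has %d unnamed columns but the model needs %d features",
              what, ncol(x), length(needed))
    x
  }
}

#' Predict class labels and probabilities from a fitted cascade
#'
#' New samples are standardized with the training normalization statistics,
#' propagated through every retained cascade layer (each layer's score
#' columns, plus the re-injected scanned features, feed the next layer
#' exactly as during training), and finally classified by majority vote of
#' the last layer's classifiers. The vote fraction is reported as the
#' positive-class probability; a sample with exactly half the votes (tie)
#' is labelled negative.
#'
#' @param object a fitted [deep_centroid()] model.
#' @param newdata samples-by-features matrix carrying at least the model's
#'   required features (matched by column name when present).
#' @param newdata2 secondary omics matrix, required iff the model was
#'   fitted with one.
#' @param ... unused.
#' @return A `data.frame` with columns `sample_id`,
#'   `probability_positive` and `predicted_label`, and attribute
#'   `n_voters` (the final layer's classifier count).
#' @export
predict.deep_centroid <- function(object, newdata, newdata2 = NULL, ...) {
  newdata <- check_matrix(newdata, "newdata")
  needs_x2 <- !is.null(object$concat_names) || !is.null(object$norm2)
  if (needs_x2 && is.null(newdata2))
    stop_dc("this model was fitted on two omics matrices; supply newdata2")
  if (!is.null(newdata2)) newdata2 <- check_matrix(newdata2, "newdata2")

  sample_ids <- rownames(newdata) %||% as.character(seq_len(nrow(newdata)))

  if (!is.null(object$concat_names)) {
    x1 <- cbind(align_features(newdata, object$concat_names$primary),
                align_features(newdata2, object$concat_names$secondary,
                               "newdata2"))
  } else {
    x1 <- align_features(newdata, object$feature_names)
  }
  z1 <- zscore_apply(object$norm, x1)

  z2 <- NULL
  if (!is.null(object$norm2)) {
    x2 <- align_features(newdata2, object$feature_names2, "newdata2")
    z2 <- zscore_apply(object$norm2, x2)
  }
  reinject_block <- cbind(
    if (length(object$reinject_idx))
      z1[, object$reinject_idx, drop = FALSE],
    if (length(object$reinject_idx2))
      z2[, object$reinject_idx2, drop = FALSE])
  if (!is.null(reinject_block) && ncol(reinject_block) == 0)
    reinject_block <- NULL

  k_final <- length(object$layers)
  input <- z1
  if (k_final > 1) {
    for (k in seq_len(k_final - 1L)) {
      input <- augment_features(object$layers[[k]], input, reinject_block,
                                object$config)
    }
  }
  final <- object$layers[[k_final]]
  base <- resolve_base_classifier(object$config$base_classifier)
  votes <- vapply(final$classifiers, function(cl) {
    as.integer(base$score(cl$state, input[, cl$set, drop = FALSE]) > 0)
  }, integer(nrow(input)))
  votes <- matrix(votes, nrow = nrow(input))
  prob <- rowMeans(votes)
  out <- data.frame(sample_id = sample_ids,
                    probability_positive = prob,
                    predicted_label = as.integer(prob > 0.5),
                    stringsAsFactors = FALSE)
  attr(out, "n_voters") <- length(final$classifiers)
  out
}

#' Rank features by the performance of the classifiers containing them
#'
#' A feature's importance is the mean out-of-bag validation MCC of all
#' surviving first-layer base classifiers whose feature set contains it —
#' features carried by high-performing classifiers rank highest. Only
#' first-layer classifiers are used: deeper layers operate on derived score
#' columns that do not correspond to original features. Features present in
#' no surviving classifier are excluded from the table.
#'
#' @param model a fitted [deep_centroid()].
#' @param top_k number of top-ranked features to return (default 50).
#' @return A `data.frame` sorted by decreasing importance with columns
#'   `feature_name`, `importance` and `n_classifiers_containing`.
#' @export
rank_important_features <- function(model, top_k = 50) {
  stopifnot(inherits(model, "deep_centroid"))
  if (top_k < 1) stop_dc("top_k must be >= 1")
  p <- model$scan_plan$n_features_total
  total <- numeric(p); count <- integer(p)
  for (cl in model$layers[[1]]$classifiers) {
    total[cl$set] <- total[cl$set] + cl$val_mcc
    count[cl$set] <- count[cl$set] + 1L
  }
  present <- which(count > 0L)
  tab <- data.frame(feature_name = model$feature_names[present],
                    importance = total[present] / count[present],
                    n_classifiers_containing = count[present],
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$feature_name), , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, top_k)
}
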