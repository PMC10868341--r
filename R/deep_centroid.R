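#' Fit a deep centroid cascade classifier
#'
#' Trains a deep cascade ensemble for binary classification of
#' high-dimensional omics data. The input matrix is z-score normalized
#' (statistics learned on the training data and stored in the model), then
#' scanned into many feature sets, each feeding one nearest-centroid base
#' classifier. Every layer draws a balanced with-replacement resample per
#' classifier, prunes classifiers whose out-of-bag MCC falls at or below the
#' pruning threshold, and passes the survivors' signed centroid-distance
#' scores — concatenated with the re-injected scanned features — to the next
#' layer. Training stops when the layer-level out-of-bag MCC no longer
#' improves (or at `max_layers`); prediction uses the last retained layer's
#' classifiers by majority vote.
#'
#' For paired multi-omics input, `x2` is either concatenated with `x` as
#' first-layer input (`fusion = "concatenate"`) or scanned and used only as
#' additional re-injected features for the deeper layers
#' (`fusion = "reinject"`), which prevents premature convergence without
#' widening the first layer.
#'
#' @param x numeric samples-by-features matrix (row names are sample IDs,
#'   column names feature names).
#' @param y binary labels: 0/1 vector (1 = positive class), optionally
#'   named by sample ID for alignment with `x`.
#' @param x2 optional paired secondary omics matrix (same samples, same
#'   row order or matching row names).
#' @param config a [dc_config()]; individual fields may be overridden via
#'   `...`.
#' @param ... named [dc_config()] fields overriding `config`, e.g.
#'   `n_feature_sets = 100`.
#' @param gene_sets named list of character vectors (required when
#'   `scan_strategy = "gene_sets"`), e.g. from [read_gmt()].
#' @param verbose print a per-layer log line (trained, pruned, survivors,
#'   layer oob MCC, seconds).
#' @return An object of class `"deep_centroid"`; see Details. Use
#'   [predict.deep_centroid()] for new samples and
#'   [rank_important_features()] for feature ranking.
#' @details The returned object contains `layers` (the retained cascade
#'   layers), `layer_vals` (their oob validation MCCs), `scan_plan`,
#'   `config`, `stop_reason` (`"no_improvement"` or `"max_layers"`), the
#'   stored normalization statistics, and the feature names required at
#'   prediction time.
#' @examples
#' sim <- simulate_omics(n_samples = 80, n_features = 300,
#'                       n_informative = 30, effect_size = 1.5, seed = 1)
#' fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 50, seed = 1)
#' fit
#' pred <- predict(fit, sim$x_independent)
#' mcc(truth = sim$y_independent, pred = pred$predicted_label)
#' @seealso [dc_config()], [repeated_cv()], [simulate_omics()]
#' @export
deep_centroid <- function(x, y, x2 = NULL, config = dc_config(), ...,
                          gene_sets = NULL, verbose = FALSE) {
  cl <- match.call()
  config <- modify_config(config, ...)
  x <- check_matrix(x)
  y <- align_labels(x, y)
  if (length(y) < 4 || sum(y == 1L) < 2 || sum(y == 0L) < 2)
    stop_dc("training needs >= 4 samples with >= 2 per class")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  has_x2 <- !is.null(x2)
  if (has_x2) {
    x2 <- check_matrix(x2, "x2")
    if (!is.null(rownames(x2)) && !is.null(rownames(x))) {
      missing <- setdiff(rownames(x), rownames(x2))
      if (length(missing))
        stop_dc("x2 lacks samples: %s",
                paste(utils::head(missing, 5), collapse = ", "))
      x2 <- x2[rownames(x), , drop = FALSE]
    } else if (nrow(x2) != nrow(x)) {
      stop_dc("x and x2 have different sample counts")
    }
    if (is.null(colnames(x2))) colnames(x2) <- paste0("x2.", seq_len(ncol(x2)))
    if (any(colnames(x2) %in% colnames(x)))
      stop_dc("x and x2 share feature names; make them unique")
  }

  ## --- layer-1 input and normalization ------------------------------------
  concat <- has_x2 && config$fusion == "concatenate"
  x1 <- if (concat) cbind(x, x2) else x
  norm <- zscore_fit(x1)
  z1 <- norm$x; norm$x <- NULL
  feature_names <- colnames(x1)

  norm2 <- NULL; z2 <- NULL
  if (has_x2 && config$fusion == "reinject") {
    norm2 <- zscore_fit(x2)
    z2 <- norm2$x; norm2$x <- NULL
  }

  ## --- feature scanning ----------------------------------------------------
  plan <- switch(config$scan_strategy,
    random = random_scan(ncol(z1), config$n_feature_sets,
                         config$set_size_min,
                         min(config$set_size_max, ncol(z1)),
                         seed = derive_seed(config$seed, 1, 1)),
    sliding_window = sliding_window_scan(ncol(z1), config$n_feature_sets,
                                         min(config$window_size, ncol(z1))),
    gene_sets = {
      if (is.null(gene_sets))
        stop_dc("scan_strategy = \"gene_sets\" requires `gene_sets`")
      gene_set_scan(feature_names, gene_sets, config$min_overlap)
    })

  ## --- re-injection block --------------------------------------------------
  ## union of scanned columns (deduplicated), not per-set copies: identical
  ## information at linear memory
  reinject_idx <- if (config$reinject)
    sort(unique(unlist(plan$feature_sets))) else integer(0)
  plan2 <- NULL; reinject_idx2 <- integer(0)
  if (!is.null(z2)) {
    plan2 <- random_scan(ncol(z2), config$n_feature_sets,
                         min(config$set_size_min, ncol(z2)),
                         min(config$set_size_max, ncol(z2)),
                         seed = derive_seed(config$seed, 1, 2))
    reinject_idx2 <- sort(unique(unlist(plan2$feature_sets)))
  }
  reinject_block <- cbind(
    if (length(reinject_idx)) z1[, reinject_idx, drop = FALSE],
    if (length(reinject_idx2)) z2[, reinject_idx2, drop = FALSE])
  if (!is.null(reinject_block) && ncol(reinject_block) == 0)
    reinject_block <- NULL

  ## --- cascade -------------------------------------------------------------
  layers <- list(); vals <- numeric(0)
  input_k <- z1
  sets_k <- plan$feature_sets
  best <- 0L; bad <- 0L
  stop_reason <- "max_layers"
  for (k in seq_len(config$max_layers)) {
    t0 <- proc.time()[["elapsed"]]
    layer <- train_layer(input_k, y, sets_k, config,
                         seed = derive_seed(config$seed, k, 3))
    layer$layer_index <- k
    layers[[k]] <- layer
    vals[k] <- layer$val_mcc
    if (verbose)
      message(sprintf(
        "layer %d: trained %d, pruned %d, survivors %d, oob MCC %.4f (%.1fs)",
        k, layer$n_trained, layer$n_pruned, length(layer$classifiers),
        layer$val_mcc, proc.time()[["elapsed"]] - t0))
    if (best == 0L || vals[k] > vals[best]) {
      best <- k; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > config$patience) { stop_reason <- "no_improvement"; break }
    }
    if (k == config$max_layers) break
    input_k <- augment_features(layer, input_k, reinject_block, config)
    sets_k <- deep_layer_sets(ncol(input_k), config,
                              seed = derive_seed(config$seed, k + 1L, 4))
  }
  layers <- layers[seq_len(best)]  # best prefix only
  vals <- vals[seq_len(best)]
  if (verbose)
    message(sprintf("stopped after layer %d (%s); retained %d layer(s)",
                    length(vals) + bad, stop_reason, best))

  structure(list(layers = layers, layer_vals = vals,
                 scan_plan = plan, scan_plan2 = plan2,
                 config = config, stop_reason = stop_reason,
                 norm = norm, norm2 = norm2,
                 feature_names = feature_names,
                 feature_names2 = if (!is.null(z2)) colnames(x2),
                 concat_names = if (concat)
                   list(primary = colnames(x), secondary = colnames(x2)),
                 reinject_idx = reinject_idx,
                 reinject_idx2 = reinject_idx2,
                 n_samples = nrow(x),
                 call = cl),
            class = "deep_centroid")
}

#' @export
print.deep_centroid <- function(x, ...) {
  cat("Deep centroid cascade classifier\n")
  cat(sprintf("  layers retained: %d (stop: %s)\n",
              length(x$layers), x$stop_reason))
  cat(sprintf("  scanning: %s, %d feature sets over %d features\n",
              x$scan_plan$strategy, length(x$scan_plan$feature_sets),
              x$scan_plan$n_features_total))
  last <- x$layers[[length(x$layers)]]
  cat(sprintf("  final layer: %d voting classifiers, oob MCC %.4f\n",
              length(last$classifiers), last$val_mcc))
  invisible(x)
}

#' @export
summary.deep_centroid <- function(object, ...) {
  tab <- data.frame(
    layer = vapply(object$layers, `[[`, 0L, "layer_index"),
    trained = vapply(object$layers, `[[`, 0L, "n_trained"),
    pruned = vapply(object$layers, `[[`, 0L, "n_pruned"),
    survivors = vapply(object$layers,
                       function(l) length(l$classifiers), 0L),
    oob_mcc = object$layer_vals)
  structure(list(layers = tab, config = object$config,
                 stop_reason = object$stop_reason,
                 n_samples = object$n_samples),
            class = "summary.deep_centroid")
}

#' @export
print.summary.deep_centroid <- function(x, ...) {
  cat("Deep centroid cascade classifier\n\n")
  cat(sprintf("Training samples: %d; stop reason: %s\n\n",
              x$n_samples, x$stop_reason))
  print(x$layers, row.names = FALSE)
  cat(sprintf(paste0("\nConfig: %d %s feature sets, sizes %d-%d, sampling",
                     " coefficient %.2f,\n  prune threshold %s, patience %d,",
                     " max layers %d, seed %d\n"),
              x$config$n_feature_sets, x$config$scan_strategy,
              x$config$set_size_min, x$config$set_size_max,
              x$config$sampling_coefficient,
              format(x$config$prune_threshold), x$config$patience,
              x$config$max_layers, x$config$seed))
  invisible(x)
}

#' @export
plot.deep_centroid <- function(x, ...) {
  plot(seq_along(x$layer_vals), x$layer_vals, type = "b", pch = 19,
       xlab = "cascade layer", ylab = "layer oob MCC",
       main = "Cascade convergence", xaxt = "n", ...)
  graphics::axis(1, at = seq_along(x$layer_vals))
  invisible(x)
}
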