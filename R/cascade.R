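#' Run configuration for the deep centroid cascade
#'
#' Collects every tunable of the method with its default. Defaults follow
#' the method's stated configuration: 500 random feature sets of 10--200
#' features, sampling coefficient 0.65, pruning threshold 0, sliding window
#' width 100 for the ablation comparator.
#'
#' @param scan_strategy `"random"` (default), `"sliding_window"` or
#'   `"gene_sets"`.
#' @param n_feature_sets number of feature sets per scan (default 500).
#' @param set_size_min,set_size_max random-scan set size bounds
#'   (defaults 10, 200).
#' @param window_size sliding-window width (default 100).
#' @param sampling_coefficient fraction of with-replacement draws allocated
#'   to the minority class, in (0, 1) (default 0.65).
#' @param coefficient_class `"minority"` (default) or `"positive"`: which
#'   class the sampling coefficient targets.
#' @param prune_threshold base classifiers with out-of-bag MCC at or below
#'   this value are removed (default 0).
#' @param max_layers hard cap on cascade depth (default 20).
#' @param patience number of consecutive non-improving layers tolerated
#'   before stopping (default 0: stop at the first non-improvement; an
#'   exactly equal layer MCC counts as non-improvement).
#' @param base_classifier `"nearest_centroid"` or a [base_classifier()]
#'   object.
#' @param distance distance metric for the built-in nearest-centroid
#'   learner (default `"euclidean"`).
#' @param reinject logical: re-inject the scanned original features at
#'   every cascade layer (default `TRUE`).
#' @param augment_mode `"signed"` (default): each surviving classifier
#'   contributes one signed distance-difference score column to the next
#'   layer; `"distances"`: two raw distance columns per classifier.
#' @param fusion multi-omics mode: `"concatenate"` (default; both matrices
#'   are joined as first-layer input) or `"reinject"` (the secondary
#'   matrix's scanned features only enter the re-injection block of deeper
#'   layers).
#' @param min_overlap minimum gene-set overlap for gene-set scanning
#'   (default 10).
#' @param seed root seed; all randomness derives from it.
#' @return A list of class `"dc_config"`.
#' @examples
#' cfg <- dc_config(n_feature_sets = 100, seed = 7)
#' cfg$sampling_coefficient
#' @export
dc_config <- function(scan_strategy = c("random", "sliding_window",
                                        "gene_sets"),
                      n_feature_sets = 500,
                      set_size_min = 10, set_size_max = 200,
                      window_size = 100,
                      sampling_coefficient = 0.65,
                      coefficient_class = c("minority", "positive"),
                      prune_threshold = 0,
                      max_layers = 20, patience = 0,
                      base_classifier = "nearest_centroid",
                      distance = c("euclidean", "correlation"),
                      reinject = TRUE,
                      augment_mode = c("signed", "distances"),
                      fusion = c("concatenate", "reinject"),
                      min_overlap = 10,
                      seed = 1) {
  cfg <- list(scan_strategy = match.arg(scan_strategy),
              n_feature_sets = as.integer(n_feature_sets),
              set_size_min = as.integer(set_size_min),
              set_size_max = as.integer(set_size_max),
              window_size = as.integer(window_size),
              sampling_coefficient = sampling_coefficient,
              coefficient_class = match.arg(coefficient_class),
              prune_threshold = prune_threshold,
              max_layers = as.integer(max_layers),
              patience = as.integer(patience),
              base_classifier = base_classifier,
              distance = match.arg(distance),
              reinject = isTRUE(reinject),
              augment_mode = match.arg(augment_mode),
              fusion = match.arg(fusion),
              min_overlap = as.integer(min_overlap),
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$n_feature_sets < 1) stop_dc("n_feature_sets must be >= 1")
  if (cfg$set_size_min < 1 || cfg$set_size_min > cfg$set_size_max)
    stop_dc("need 1 <= set_size_min <= set_size_max")
  if (cfg$sampling_coefficient <= 0 || cfg$sampling_coefficient >= 1)
    stop_dc("sampling_coefficient must lie strictly between 0 and 1")
  if (cfg$max_layers < 1) stop_dc("max_layers must be >= 1")
  if (cfg$patience < 0) stop_dc("patience must be >= 0")
  structure(cfg, class = "dc_config")
}

modify_config <- function(cfg, ...) {
  dots <- list(...)
  if (!length(dots)) return(cfg)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_dc("unknown config field(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  cfg$n_feature_sets <- as.integer(cfg$n_feature_sets)
  cfg$set_size_min <- as.integer(cfg$set_size_min)
  cfg$set_size_max <- as.integer(cfg$set_size_max)
  cfg$window_size <- as.integer(cfg$window_size)
  cfg$max_layers <- as.integer(cfg$max_layers)
  cfg$patience <- as.integer(cfg$patience)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
}

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror [dc_config()] arguments field for field; absent
#' keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `dc_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_dc("reading YAML configs requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  do.call(modify_config, c(list(dc_config()), vals))
}

#' Z-score normalization with stored training statistics
#'
#' `zscore_fit()` learns per-feature mean and standard deviation (population
#' denominator `n`) on training data; `zscore_apply()` standardizes any
#' matrix with those statistics, so held-out samples are always transformed
#' with training statistics only. Constant training columns (sd 0) map to 0.
#'
#' @param x numeric matrix, samples in rows (>= 2 rows for fitting).
#' @return `zscore_fit`: list with `mean`, `sd` (per feature) and the
#'   standardized training matrix `x`; `zscore_apply`: the standardized
#'   matrix.
#' @examples
#' zs <- zscore_fit(matrix(c(0, 2, 3, 3), 2))
#' zs$x  # first column (-1, 1); constant column maps to 0
#' @export
zscore_fit <- function(x) {
  x <- check_matrix(x)
  if (nrow(x) < 2) stop_dc("z-score fitting needs >= 2 samples")
  m <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, m)^2))
  stats <- list(mean = m, sd = sd_pop)
  stats$x <- zscore_apply(stats, x)
  stats
}

#' @rdname zscore_fit
#' @param stats the statistics list from [zscore_fit()].
#' @param x_new matrix with the same columns as the fitted one.
#' @export
zscore_apply <- function(stats, x_new) {
  x_new <- check_matrix(x_new, "x_new")
  if (ncol(x_new) != length(stats$mean))
    stop_dc("column count mismatch in zscore_apply")
  z <- sweep(x_new, 2, stats$mean)
  keep <- stats$sd > 0
  z[, keep] <- sweep(z[, keep, drop = FALSE], 2, stats$sd[keep], "/")
  z[, !keep] <- 0
  z
}

#' Balanced resampling with out-of-bag validation set
#'
#' Draws `length(y)` training samples with replacement such that
#' `round(coefficient * n)` draws come from the minority class (or the
#' positive class, per `coefficient_class`) and the rest from the other
#' class, pushing the training multiset toward balance on imbalanced data.
#' Samples never drawn form the out-of-bag (oob) set used to validate and
#' prune the classifier fitted on this split. Degenerate draws (a class
#' absent from the training multiset, or an empty oob set) are re-drawn up
#' to `max_retries` times.
#'
#' @param y 0/1 label vector; both classes must be present.
#' @param coefficient sampling coefficient in (0, 1) (default 0.65).
#' @param seed integer seed; a fixed seed gives an identical split.
#' @param coefficient_class `"minority"` (default) or `"positive"`.
#' @param max_retries bound on re-draws (default 100).
#' @return A list of class `"resample_split"` with `train_idx` (multiset of
#'   sample indices) and `oob_idx` (indices never drawn).
#' @examples
#' y <- rep(c(1, 0), c(30, 70))
#' sp <- resample_balanced(y, seed = 1)
#' sum(y[sp$train_idx] == 1)  # 65 minority-class draws
#' @export
resample_balanced <- function(y, coefficient = 0.65, seed = 1,
                              coefficient_class = c("minority", "positive"),
                              max_retries = 100) {
  coefficient_class <- match.arg(coefficient_class)
  y <- as.integer(y)
  n <- length(y)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (!length(pos) || !length(neg))
    stop_dc("resample_balanced needs both classes present")
  if (coefficient <= 0 || coefficient >= 1)
    stop_dc("coefficient must lie strictly between 0 and 1")
  target <- if (coefficient_class == "positive") pos
            else if (length(pos) <= length(neg)) pos else neg
  other <- if (identical(target, pos)) neg else pos
  n_target <- round(coefficient * n)
  if (n_target < 1 || n_target > n - 1)
    stop_dc("coefficient %.3f leaves no draws for one class at n = %d",
            coefficient, n)
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      train_idx <- c(sample(target, n_target, replace = TRUE),
                     sample(other, n - n_target, replace = TRUE))
      oob_idx <- setdiff(seq_len(n), unique(train_idx))
      ok <- any(y[train_idx] == 1L) && any(y[train_idx] == 0L) &&
        length(oob_idx) > 0L
      if (ok)
        return(structure(list(train_idx = train_idx, oob_idx = oob_idx),
                         class = "resample_split"))
    }
    stop_dc("no valid resample after %d retries (data too small?)",
            max_retries)
  })
}

#' Train one cascade layer
#'
#' Fits one base classifier per feature set, each on its own balanced
#' with-replacement resample, evaluates every classifier by MCC on its own
#' out-of-bag samples, and removes those with oob MCC at or below the
#' pruning threshold. The layer's own validation MCC is the MCC of the
#' surviving classifiers' majority vote over the union of oob samples,
#' where each sample is voted on only by classifiers for which it is
#' out-of-bag.
#'
#' @param x_layer numeric matrix (already normalized) whose columns cover
#'   every index referenced by `feature_sets`.
#' @param y 0/1 labels, one per row.
#' @param feature_sets list of integer column-index vectors (e.g.
#'   `plan$feature_sets`).
#' @param config a [dc_config()].
#' @param seed layer seed; per-classifier seeds are derived from it.
#' @return A list of class `"cascade_layer"`: `classifiers` (survivors,
#'   each with `set`, `set_id`, `state`, `val_mcc`, `split`), `val_mcc`,
#'   `n_trained`, `n_pruned`, `layer_index`.
#' @export
train_layer <- function(x_layer, y, feature_sets, config = dc_config(),
                        seed = config$seed) {
  x_layer <- check_matrix(x_layer, "x_layer")
  y <- as.integer(y)
  base <- resolve_base_classifier(config$base_classifier)
  n <- nrow(x_layer)
  max_idx <- max(vapply(feature_sets, max, 0L))
  if (max_idx > ncol(x_layer))
    stop_dc("feature set references column %d but x_layer has %d columns",
            max_idx, ncol(x_layer))

  classifiers <- vector("list", length(feature_sets))
  for (i in seq_along(feature_sets)) {
    set <- feature_sets[[i]]
    split <- resample_balanced(y, config$sampling_coefficient,
                               seed = derive_seed(seed, i),
                               coefficient_class = config$coefficient_class)
    xs <- x_layer[, set, drop = FALSE]
    state <- base$fit(xs[split$train_idx, , drop = FALSE],
                      y[split$train_idx])
    oob_scores <- base$score(state, xs[split$oob_idx, , drop = FALSE])
    val <- mcc(truth = y[split$oob_idx],
               pred = as.integer(oob_scores > 0))
    classifiers[[i]] <- list(set = as.integer(set),
                             set_id = attr(set, "set_id") %||% i,
                             state = state, val_mcc = val,
                             split = split,
                             oob_pred = as.integer(oob_scores > 0))
  }

  vals <- vapply(classifiers, `[[`, 0, "val_mcc")
  keep <- vals > config$prune_threshold
  if (!any(keep))
    stop_dc(paste("all %d base classifiers pruned at oob MCC threshold %s;",
                  "the data may carry no signal"),
            length(classifiers), format(config$prune_threshold))
  survivors <- classifiers[keep]

  ## layer-level oob majority vote
  votes_pos <- integer(n); votes_n <- integer(n)
  for (cl in survivors) {
    oob <- cl$split$oob_idx
    votes_pos[oob] <- votes_pos[oob] + cl$oob_pred
    votes_n[oob] <- votes_n[oob] + 1L
  }
  voted <- votes_n > 0L
  layer_pred <- as.integer(votes_pos[voted] / votes_n[voted] > 0.5)
  layer_val <- mcc(truth = y[voted], pred = layer_pred)

  structure(list(classifiers = survivors,
                 val_mcc = layer_val,
                 n_trained = length(feature_sets),
                 n_pruned = sum(!keep),
                 layer_index = NA_integer_),
            class = "cascade_layer")
}

## Score every classifier of a fitted layer on a full matrix; returns the
## augmentation columns (one signed score per classifier, or two raw
## distances in "distances" mode), ordered by set_id.
layer_scores <- function(layer, x_input, config) {
  base <- resolve_base_classifier(config$base_classifier)
  cols <- lapply(layer$classifiers, function(cl) {
    xs <- x_input[, cl$set, drop = FALSE]
    if (config$augment_mode == "distances" &&
        inherits(cl$state, "centroid_model")) {
      cbind(dist_to(xs, cl$state$centroid_neg, cl$state$distance),
            dist_to(xs, cl$state$centroid_pos, cl$state$distance))
    } else {
      matrix(base$score(cl$state, xs), ncol = 1)
    }
  })
  out <- do.call(cbind, cols)
  colnames(out) <- NULL
  out
}

#' Build the next layer's input matrix
#'
#' Concatenates one score column per surviving classifier (in `set_id`
#' order) with the re-injected scanned feature columns, in that order. The
#' result is deterministic given the layer and inputs.
#'
#' @param layer a fitted `"cascade_layer"`.
#' @param x_input the matrix the layer's classifiers were trained on.
#' @param reinject_cols matrix of re-injected scanned columns (or `NULL`
#'   for score columns only).
#' @param config a [dc_config()].
#' @return Numeric matrix `[scores | reinjected]`.
#' @export
augment_features <- function(layer, x_input, reinject_cols = NULL,
                             config = dc_config()) {
  stopifnot(inherits(layer, "cascade_layer"))
  x_input <- check_matrix(x_input, "x_input")
  sc <- layer_scores(layer, x_input, config)
  if (is.null(reinject_cols)) return(sc)
  reinject_cols <- check_matrix(reinject_cols, "reinject_cols")
  if (nrow(reinject_cols) != nrow(sc))
    stop_dc("re-injected block has %d rows, scores have %d",
            nrow(reinject_cols), nrow(sc))
  cbind(sc, reinject_cols)
}

## Random feature sets for deep layers, drawn over the augmented width with
## the same size law as the first-layer random scan (bounds clamped to the
## available width).
deep_layer_sets <- function(width, config, seed) {
  smax <- min(config$set_size_max, width)
  smin <- min(config$set_size_min, smax)
  plan <- random_scan(width, n_sets = config$n_feature_sets,
                      size_min = smin, size_max = smax, seed = seed)
  plan$feature_sets
}
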