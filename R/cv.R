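#' Learner wrappers for the evaluation harness
#'
#' The cross-validation and validation harnesses are classifier-agnostic:
#' a learner is a list with `fit(x, y, seed)` returning a fitted object and
#' `predict(object, x)` returning a data frame with a ranking column
#' `score` (higher = more positive) and a hard `label` column.
#' `cascade_learner()` wraps [deep_centroid()] (the prediction score is the
#' final-layer vote fraction); `ncc_learner()` wraps a single
#' nearest-centroid classifier over all features — the natural baseline the
#' cascade is meant to beat.
#'
#' @param config a [dc_config()] for the cascade.
#' @param ... [dc_config()] overrides.
#' @return A list of class `"dc_learner"` with `fit`, `predict`, `name`.
#' @export
cascade_learner <- function(config = dc_config(), ...) {
  config <- modify_config(config, ...)
  structure(list(
    fit = function(x, y, seed) deep_centroid(x, y, config = config,
                                             seed = as.integer(seed)),
    predict = function(object, x) {
      p <- predict(object, x)
      data.frame(score = p$probability_positive,
                 label = p$predicted_label)
    },
    name = paste0("deep_centroid(", config$scan_strategy, ")")),
    class = "dc_learner")
}

#' @rdname cascade_learner
#' @param distance distance metric for the baseline centroid classifier.
#' @export
ncc_learner <- function(distance = "euclidean") {
  structure(list(
    fit = function(x, y, seed) {
      stats <- zscore_fit(x)
      z <- stats$x; stats$x <- NULL
      list(stats = stats,
           model = fit_centroid(z, y, distance = distance))
    },
    predict = function(object, x) {
      s <- score_centroid(object$model, zscore_apply(object$stats, x))
      data.frame(score = s, label = as.integer(s > 0))
    },
    name = paste0("ncc(", distance, ")")),
    class = "dc_learner")
}

stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' The standard evaluation harness: `repeats` rounds of stratified
#' `k`-fold cross-validation, refitting the learner from scratch on every
#' training split and scoring the held-out fold with MCC, AUC, accuracy
#' and F1. Fold assignments and refit seeds all derive from `seed`, so a
#' report is exactly reproducible and two learners evaluated under the
#' same seed see identical folds.
#'
#' @param x samples-by-features matrix.
#' @param y 0/1 labels (each class must have at least `k` members).
#' @param learner a [cascade_learner()], [ncc_learner()] or compatible
#'   list.
#' @param k folds (default 5).
#' @param repeats repetitions (default 10).
#' @param seed root seed.
#' @return An object of class `"cv_report"`: `folds` (one row per
#'   repeat-fold with all metrics), `aggregate` (mean and sd per metric),
#'   `k`, `repeats`, `seed`, `learner`.
#' @export
repeated_cv <- function(x, y, learner = cascade_learner(), k = 5,
                        repeats = 10, seed = 1) {
  x <- check_matrix(x)
  y <- align_labels(x, y)
  n_min <- min(sum(y == 1L), sum(y == 0L))
  if (n_min < k)
    stop_dc("smallest class has %d samples < k = %d folds; use a smaller k",
            n_min, k)
  rows <- vector("list", repeats * k)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, k, derive_seed(seed, r, 11))
    for (f in seq_len(k)) {
      test <- folds == f
      fit <- learner$fit(x[!test, , drop = FALSE], y[!test],
                         derive_seed(seed, r, f))
      pr <- learner$predict(fit, x[test, , drop = FALSE])
      rows[[(r - 1) * k + f]] <-
        cbind(data.frame(repeat_id = r, fold = f, n_test = sum(test)),
              metric_row(y[test], pr$label, pr$score))
    }
  }
  folds_df <- do.call(rbind, rows)
  metrics <- c("mcc", "auc", "accuracy", "f1")
  structure(list(folds = folds_df,
                 aggregate = list(
                   mean = vapply(folds_df[metrics], mean, 0),
                   sd = vapply(folds_df[metrics], stats::sd, 0)),
                 k = k, repeats = repeats, seed = seed,
                 learner = learner$name %||% "custom"),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold stratified cross-validation — %s (seed %d)\n",
              x$repeats, x$k, x$learner, x$seed))
  m <- x$aggregate$mean; s <- x$aggregate$sd
  for (nm in names(m))
    cat(sprintf("  %-9s %.4f (sd %.4f)\n", nm, m[nm], s[nm]))
  invisible(x)
}

#' Independent validation on a disjoint cohort
#'
#' Trains on one cohort and evaluates on another (e.g. an external
#' validation set from a different source). Because the learner is
#' seed-dependent, the model is refitted `n_runs` times with derived seeds
#' and the test metrics are averaged. Train and test sample IDs must be
#' disjoint.
#'
#' @param x_train,y_train training cohort.
#' @param x_test,y_test independent cohort (disjoint sample IDs).
#' @param learner see [repeated_cv()].
#' @param n_runs number of refits averaged (default 3).
#' @param seed root seed.
#' @return An object of class `"validation_report"` with `runs` (per-run
#'   metrics) and `aggregate` (their mean and sd).
#' @export
independent_validation <- function(x_train, y_train, x_test, y_test,
                                   learner = cascade_learner(),
                                   n_runs = 3, seed = 1) {
  x_train <- check_matrix(x_train, "x_train")
  x_test <- check_matrix(x_test, "x_test")
  if (!is.null(rownames(x_train)) && !is.null(rownames(x_test))) {
    shared <- intersect(rownames(x_train), rownames(x_test))
    if (length(shared))
      stop_dc("train and test cohorts share sample IDs: %s%s",
              paste(utils::head(shared, 5), collapse = ", "),
              if (length(shared) > 5) ", ..." else "")
  }
  y_train <- align_labels(x_train, y_train)
  y_test <- align_labels(x_test, y_test)
  rows <- lapply(seq_len(n_runs), function(r) {
    fit <- learner$fit(x_train, y_train, derive_seed(seed, r, 21))
    pr <- learner$predict(fit, x_test)
    cbind(data.frame(run = r), metric_row(y_test, pr$label, pr$score))
  })
  runs <- do.call(rbind, rows)
  metrics <- c("mcc", "auc", "accuracy", "f1")
  structure(list(runs = runs,
                 aggregate = list(
                   mean = vapply(runs[metrics], mean, 0),
                   sd = vapply(runs[metrics], stats::sd, 0)),
                 n_runs = n_runs, seed = seed,
                 learner = learner$name %||% "custom"),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Independent validation — %s (%d run(s), seed %d)\n",
              x$learner, x$n_runs, x$seed))
  m <- x$aggregate$mean; s <- x$aggregate$sd
  for (nm in names(m))
    cat(sprintf("  %-9s %.4f (sd %.4f)\n", nm, m[nm], s[nm]))
  invisible(x)
}

#' Paired ablation runner
#'
#' Evaluates several learner variants (e.g. random versus sliding-window
#' scanning, or different base classifiers) by cross-validation on
#' identical folds and seeds, so per-fold metrics can be compared pairwise.
#'
#' @param x,y data as in [repeated_cv()].
#' @param variants named list of learners; defaults to the scanning
#'   ablation pair (random vs sliding-window feature scanning).
#' @param k,repeats,seed as in [repeated_cv()].
#' @return An object of class `"ablation_report"`: `reports` (one
#'   `cv_report` per variant) and `paired` (long-format fold metrics with
#'   a `variant` column, aligned by repeat and fold).
#' @export
run_ablation <- function(x, y,
                         variants = list(
                           random = cascade_learner(scan_strategy = "random"),
                           sliding_window =
                             cascade_learner(scan_strategy = "sliding_window")),
                         k = 5, repeats = 1, seed = 1) {
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop_dc("variants must be a named list of learners")
  reports <- lapply(variants, function(lrn)
    repeated_cv(x, y, lrn, k = k, repeats = repeats, seed = seed))
  paired <- do.call(rbind, lapply(names(reports), function(nm)
    cbind(data.frame(variant = nm), reports[[nm]]$folds)))
  structure(list(reports = reports, paired = paired, seed = seed),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("Ablation comparison (identical folds per variant)\n")
  for (nm in names(x$reports)) {
    m <- x$reports[[nm]]$aggregate$mean
    cat(sprintf("  %-16s mcc %.4f  auc %.4f  accuracy %.4f  f1 %.4f\n",
                nm, m["mcc"], m["auc"], m["accuracy"], m["f1"]))
  }
  invisible(x)
}

#' Export a cross-validation report
#'
#' Writes the long-format fold table plus an aggregate block, as TSV or
#' JSON by extension.
#'
#' @param report a `cv_report`.
#' @param path output path ending in `.tsv` or `.json`.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(folds = report$folds,
                              aggregate = report$aggregate,
                              k = report$k, repeats = report$repeats,
                              seed = report$seed, learner = report$learner),
                         path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    utils::write.table(report$folds, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
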