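#' Feature scanning: random subsets, sliding windows, gene sets
#'
#' Scanning produces the feature sets that define the ensemble's base
#' classifiers: each set feeds one nearest-centroid classifier. Because
#' features in omics matrices are ordered by name or identifier, adjacent
#' columns rarely share biology; the default strategy therefore draws many
#' random subsets of varying sizes rather than contiguous windows.
#'
#' A scan plan is a list of class `"scan_plan"` with fields:
#' \describe{
#'   \item{feature_sets}{list of integer index vectors (1-based columns);
#'     each has attributes `set_id` and `source`.}
#'   \item{n_features_total}{number of columns of the scanned matrix.}
#'   \item{strategy}{`"random"`, `"sliding_window"` or `"gene_sets"`.}
#'   \item{seed}{the seed the plan was drawn under (NA when deterministic).}
#' }
#'
#' @name scanning
NULL

new_scan_plan <- function(sets, n_features, strategy, seed = NA_integer_) {
  sets <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    attr(s, "set_id") <- i
    if (is.null(attr(s, "source"))) attr(s, "source") <- strategy
    s
  })
  structure(list(feature_sets = sets,
                 n_features_total = as.integer(n_features),
                 strategy = strategy,
                 seed = seed),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  sizes <- lengths(x$feature_sets)
  cat(sprintf("Scan plan: %d feature sets over %d features (%s)\n",
              length(x$feature_sets), x$n_features_total, x$strategy))
  cat(sprintf("  set sizes: min %d / median %d / max %d\n",
              min(sizes), as.integer(stats::median(sizes)), max(sizes)))
  invisible(x)
}

#' Random feature scanning
#'
#' Draws `n_sets` feature subsets; each set's size is uniform on
#' `[size_min, size_max]` and its members are sampled without replacement
#' within the set. Sets may overlap with one another. Defaults follow the
#' method's stated configuration: 500 sets of 10--200 features.
#'
#' @param n_features number of columns available.
#' @param n_sets number of sets to draw (default 500).
#' @param size_min,size_max inclusive bounds on set size (defaults 10, 200).
#' @param seed integer seed; the same seed always yields the same plan.
#' @return A `scan_plan`.
#' @examples
#' plan <- random_scan(1000, n_sets = 20, seed = 1)
#' range(lengths(plan$feature_sets))
#' @export
random_scan <- function(n_features, n_sets = 500, size_min = 10,
                        size_max = 200, seed = 1) {
  n_features <- as.integer(n_features)
  if (size_min < 1 || size_min > size_max)
    stop_dc("need 1 <= size_min <= size_max (got %s, %s)", size_min, size_max)
  if (size_max > n_features)
    stop_dc("size_max (%d) exceeds the number of features (%d)",
            as.integer(size_max), n_features)
  if (n_sets < 1) stop_dc("n_sets must be >= 1")
  sets <- with_seed(seed, {
    sizes <- sample.int(size_max - size_min + 1L, n_sets, replace = TRUE) +
      as.integer(size_min) - 1L
    lapply(sizes, function(s) sample.int(n_features, s, replace = FALSE))
  })
  new_scan_plan(sets, n_features, "random", as.integer(seed))
}

#' Sliding-window feature scanning
#'
#' The contiguous-window comparator used in the scanning ablation: set `k`
#' covers `window` consecutive columns starting at `k * step` with
#' `step = max(1, floor(n_features / n_sets))`. Windows that would run past
#' the last column are shifted left so every set keeps exactly `window`
#' members and the final column is always covered.
#'
#' @param n_features number of columns available.
#' @param n_sets number of windows (default 500).
#' @param window window width (default 100, the median random-set size).
#' @return A `scan_plan` (deterministic; no seed involved).
#' @examples
#' plan <- sliding_window_scan(300, n_sets = 3)
#' lapply(plan$feature_sets, range)
#' @export
sliding_window_scan <- function(n_features, n_sets = 500, window = 100) {
  n_features <- as.integer(n_features); window <- as.integer(window)
  if (window > n_features)
    stop_dc("window (%d) exceeds the number of features (%d)",
            window, n_features)
  if (n_sets < 1) stop_dc("n_sets must be >= 1")
  step <- max(1L, n_features %/% as.integer(n_sets))
  sets <- lapply(seq_len(n_sets) - 1L, function(k) {
    start <- if (k == n_sets - 1L) n_features - window  # last window ends at p
             else min(k * step, n_features - window)
    seq.int(start + 1L, start + window)
  })
  new_scan_plan(sets, n_features, "sliding_window")
}

#' Prior-knowledge gene-set scanning
#'
#' Turns curated gene sets (e.g. GO biological process or KEGG pathways read
#' from a GMT file) into feature sets by intersecting each with the matrix's
#' feature names. Sets whose overlap falls below `min_overlap` are dropped.
#'
#' @param feature_names character vector of available feature names.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param min_overlap minimum surviving members per set (default 10,
#'   matching the random-scan lower bound).
#' @return A `scan_plan` whose sets carry `source = "gene_set:<name>"`.
#' @export
gene_set_scan <- function(feature_names, gene_sets, min_overlap = 10) {
  if (!length(feature_names)) stop_dc("feature_names is empty")
  if (!length(gene_sets)) stop_dc("gene_sets is empty")
  nm <- names(gene_sets) %||% as.character(seq_along(gene_sets))
  sets <- list(); kept <- character(0)
  for (i in seq_along(gene_sets)) {
    idx <- which(feature_names %in% gene_sets[[i]])
    if (length(idx) >= min_overlap) {
      attr(idx, "source") <- paste0("gene_set:", nm[i])
      sets[[length(sets) + 1L]] <- idx
      kept <- c(kept, nm[i])
    }
  }
  n_drop <- length(gene_sets) - length(sets)
  if (n_drop > 0)
    message(sprintf("gene_set_scan: dropped %d set(s) with overlap < %d",
                    n_drop, min_overlap))
  if (!length(sets))
    stop_dc(paste("no gene set overlaps the feature names by >= %d members;",
                  "consider random_scan()"), min_overlap)
  new_scan_plan(sets, length(feature_names), "gene_sets")
}

#' Export / import a scan plan as JSON
#'
#' Plans are serialized to a small JSON sidecar so that scans can be audited
#' and reused; a round trip reproduces the plan exactly.
#'
#' @param plan a `scan_plan`.
#' @param path file path for the JSON document.
#' @return `write_scan_plan` returns `path` invisibly; `read_scan_plan`
#'   returns the `scan_plan`.
#' @export
write_scan_plan <- function(plan, path) {
  stopifnot(inherits(plan, "scan_plan"))
  doc <- list(format = "deepcentroid-scan-plan", version = 1L,
              strategy = plan$strategy,
              n_features_total = plan$n_features_total,
              seed = plan$seed,
              sources = vapply(plan$feature_sets,
                               function(s) attr(s, "source"), ""),
              feature_sets = lapply(plan$feature_sets, as.integer))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scan_plan
#' @export
read_scan_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "deepcentroid-scan-plan"))
    stop_dc("not a scan-plan file: %s", path)
  sets <- lapply(seq_along(doc$feature_sets), function(i) {
    s <- as.integer(doc$feature_sets[[i]])
    attr(s, "source") <- doc$sources[[i]]
    s
  })
  new_scan_plan(sets, doc$n_features_total, doc$strategy,
                as.integer(doc$seed %||% NA_integer_))
}
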