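guess_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a samples-by-features matrix from delimited text
#'
#' Expects one header row of names and one leading ID column. The file's
#' layout must be declared, never guessed: repository-style omics tables
#' come both ways, and silent transposition is a classic source of wrong
#' results.
#'
#' @param path TSV/CSV file path (delimiter chosen by extension, `.csv`
#'   means comma; override with `sep`).
#' @param orientation `"samples_in_rows"` (default) or
#'   `"features_in_rows"`; the latter is transposed after reading so the
#'   result is always samples x features.
#' @param sep field delimiter override.
#' @param impute `"none"` (default: any missing value is a hard error) or
#'   `"mean"` (per-feature mean imputation).
#' @return A numeric matrix with unique sample row names and feature
#'   column names; every value finite.
#' @export
read_matrix <- function(path,
                        orientation = c("samples_in_rows",
                                        "features_in_rows"),
                        sep = NULL, impute = c("none", "mean")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  df <- utils::read.table(path, sep = guess_sep(path, sep), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop_dc("%s: need an ID column plus >= 1 data column",
                            path)
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_dc("%s: duplicated IDs: %s", path, paste(dup, collapse = ", "))
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "NA")
      if (length(bad))
        stop_dc("%s: non-numeric value '%s' at row %d, column '%s'",
                path, v[bad[1]], bad[1], colnames(vals)[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "features_in_rows") m <- t(m)
  dupf <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dupf))
    stop_dc("%s: duplicated feature names: %s", path,
            paste(dupf, collapse = ", "))
  if (anyNA(m)) {
    if (impute == "none")
      stop_dc("%s: %d missing value(s); pass impute = \"mean\" to impute",
              path, sum(is.na(m)))
    for (j in which(colSums(is.na(m)) > 0)) {
      mu <- mean(m[, j], na.rm = TRUE)
      if (!is.finite(mu)) mu <- 0
      m[is.na(m[, j]), j] <- mu
    }
  }
  if (!all(is.finite(m)))
    stop_dc("%s: non-finite values after imputation", path)
  m
}

#' @rdname read_matrix
#' @param x matrix to write.
#' @param id_name header for the ID column (default `"id"`).
#' @export
write_matrix <- function(x, path, sep = NULL, id_name = "id") {
  x <- check_matrix(x)
  df <- data.frame(rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  utils::write.table(df, path, sep = guess_sep(path, sep),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a binary label table
#'
#' Reads a two-column table (sample ID, class string) and maps the declared
#' positive class to 1, the other class to 0.
#'
#' @param path TSV/CSV path.
#' @param positive name of the positive class as written in the file.
#' @param sep delimiter override.
#' @return Named integer 0/1 vector (names are sample IDs) with attribute
#'   `positive_class`.
#' @export
read_labels <- function(path, positive, sep = NULL) {
  df <- utils::read.table(path, sep = guess_sep(path, sep), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_dc("%s: need two columns (sample ID, class)", path)
  ids <- as.character(df[[1]])
  cls <- as.character(df[[2]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_dc("%s: duplicated sample IDs: %s", path, paste(dup, collapse = ", "))
  classes <- unique(cls)
  if (length(classes) > 2)
    stop_dc("%s: found %d classes (%s); exactly two are required",
            path, length(classes), paste(classes, collapse = ", "))
  if (!positive %in% classes)
    stop_dc("%s: positive class '%s' not present (classes: %s)",
            path, positive, paste(classes, collapse = ", "))
  y <- as.integer(cls == positive)
  names(y) <- ids
  attr(y, "positive_class") <- positive
  y
}

#' Inner-join a matrix with a label vector
#'
#' Keeps the samples present in both, reports how many were dropped from
#' each side, and refuses to proceed with fewer than two samples per class.
#' Labelled samples absent from the matrix are a hard error (they indicate
#' a broken upload, not a subset).
#'
#' @param x samples-by-features matrix with row names.
#' @param y named 0/1 label vector (e.g. from [read_labels()]).
#' @return `list(x = matrix, y = labels)` with identical sample order.
#' @export
join_samples <- function(x, y) {
  x <- check_matrix(x)
  if (is.null(rownames(x)) || is.null(names(y)))
    stop_dc("join_samples needs row names on x and names on y")
  unlabelled <- setdiff(rownames(x), names(y))
  orphans <- setdiff(names(y), rownames(x))
  if (length(orphans))
    stop_dc("labelled samples absent from the matrix: %s%s",
            paste(utils::head(orphans, 5), collapse = ", "),
            if (length(orphans) > 5) ", ..." else "")
  if (length(unlabelled))
    message(sprintf("join_samples: dropped %d unlabelled sample(s)",
                    length(unlabelled)))
  common <- intersect(rownames(x), names(y))
  x <- x[common, , drop = FALSE]
  y <- y[common]
  if (sum(y == 1L) < 2 || sum(y == 0L) < 2)
    stop_dc("training requires >= 2 samples per class after the join")
  list(x = x, y = y)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB GMT dialect: one set per line — set name, description,
#' then tab-separated member genes. Members are de-duplicated within a set;
#' file order is preserved.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (possibly empty for an empty
#'   file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  out <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop_dc("%s: line %d has %d field(s); GMT needs name, description and >= 1 member",
              path, i, length(fields))
    nms[i] <- fields[1]
    out[[i]] <- unique(fields[-(1:2)])
  }
  stats::setNames(out, nms)
}

## ---- model persistence ----------------------------------------------------

MODEL_FORMAT <- "deepcentroid-model"
MODEL_VERSION <- 1L

serialize_classifier <- function(cl) {
  if (!inherits(cl$state, "centroid_model"))
    stop_dc("only models with the built-in nearest-centroid base classifier can be saved")
  list(set = as.integer(cl$set), set_id = cl$set_id, val_mcc = cl$val_mcc,
       centroid_pos = unname(cl$state$centroid_pos),
       centroid_neg = unname(cl$state$centroid_neg),
       distance = cl$state$distance)
}

deserialize_classifier <- function(s) {
  state <- structure(list(centroid_pos = as.numeric(s$centroid_pos),
                          centroid_neg = as.numeric(s$centroid_neg),
                          distance = s$distance,
                          n_features = length(s$centroid_pos)),
                     class = "centroid_model")
  list(set = as.integer(s$set), set_id = as.integer(s$set_id),
       state = state, val_mcc = as.numeric(s$val_mcc))
}

#' Save / load a fitted cascade model
#'
#' Models are persisted as a versioned JSON container of plain arrays plus
#' the run configuration — no opaque binary blobs — so artifacts remain
#' auditable and portable. A save/load round trip reproduces predictions
#' bit-identically (numbers are written at full IEEE precision).
#'
#' @param model a fitted [deep_centroid()] (nearest-centroid base
#'   classifier only).
#' @param path file path for the JSON document.
#' @return `save_model` returns `path` invisibly; `load_model` the
#'   restored `deep_centroid` object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "deep_centroid"))
  doc <- list(
    format = MODEL_FORMAT, version = MODEL_VERSION,
    config = unclass(model$config),
    stop_reason = model$stop_reason,
    layer_vals = model$layer_vals,
    layers = lapply(model$layers, function(l) {
      list(layer_index = l$layer_index, val_mcc = l$val_mcc,
           n_trained = l$n_trained, n_pruned = l$n_pruned,
           classifiers = lapply(l$classifiers, serialize_classifier))
    }),
    norm = list(mean = unname(model$norm$mean), sd = unname(model$norm$sd)),
    norm2 = if (!is.null(model$norm2))
      list(mean = unname(model$norm2$mean), sd = unname(model$norm2$sd)),
    feature_names = model$feature_names,
    feature_names2 = model$feature_names2,
    concat_names = model$concat_names,
    reinject_idx = as.integer(model$reinject_idx),
    reinject_idx2 = as.integer(model$reinject_idx2),
    scan_plan = list(strategy = model$scan_plan$strategy,
                     n_features_total = model$scan_plan$n_features_total,
                     seed = model$scan_plan$seed,
                     feature_sets = lapply(model$scan_plan$feature_sets,
                                           as.integer)),
    n_samples = model$n_samples)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_dc("cannot parse model file %s: %s", path,
                            conditionMessage(e)))
  if (!identical(doc$format, MODEL_FORMAT))
    stop_dc("%s is not a deepcentroid model file", path)
  if (!identical(as.integer(doc$version), MODEL_VERSION))
    stop_dc("model format version %s not supported (expected %d)",
            doc$version %||% "<missing>", MODEL_VERSION)
  cfg <- do.call(dc_config, doc$config[setdiff(names(doc$config), NULL)])
  layers <- lapply(doc$layers, function(l) {
    structure(list(classifiers = lapply(l$classifiers,
                                        deserialize_classifier),
                   val_mcc = as.numeric(l$val_mcc),
                   n_trained = as.integer(l$n_trained),
                   n_pruned = as.integer(l$n_pruned),
                   layer_index = as.integer(l$layer_index)),
              class = "cascade_layer")
  })
  plan <- new_scan_plan(lapply(doc$scan_plan$feature_sets,
                               function(s) as.integer(unlist(s))),
                        as.integer(doc$scan_plan$n_features_total),
                        doc$scan_plan$strategy,
                        as.integer(doc$scan_plan$seed %||% NA_integer_))
  as_num <- function(v) as.numeric(unlist(v))
  structure(list(
    layers = layers, layer_vals = as_num(doc$layer_vals),
    scan_plan = plan, scan_plan2 = NULL,
    config = cfg, stop_reason = doc$stop_reason,
    norm = list(mean = as_num(doc$norm$mean), sd = as_num(doc$norm$sd)),
    norm2 = if (!is.null(doc$norm2))
      list(mean = as_num(doc$norm2$mean), sd = as_num(doc$norm2$sd)),
    feature_names = as.character(unlist(doc$feature_names)),
    feature_names2 = if (!is.null(doc$feature_names2))
      as.character(unlist(doc$feature_names2)),
    concat_names = if (!is.null(doc$concat_names))
      list(primary = as.character(unlist(doc$concat_names$primary)),
           secondary = as.character(unlist(doc$concat_names$secondary))),
    reinject_idx = as.integer(unlist(doc$reinject_idx)),
    reinject_idx2 = as.integer(unlist(doc$reinject_idx2)),
    n_samples = as.integer(doc$n_samples),
    call = NULL), class = "deep_centroid")
}

#' Write a prediction table
#'
#' @param pred result of [predict.deep_centroid()].
#' @param path output TSV path (columns `sample_id`,
#'   `probability_positive`, `predicted_label`).
#' @export
write_predictions <- function(pred, path) {
  utils::write.table(pred, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a feature-importance table
#'
#' @param tab result of [rank_important_features()].
#' @param path output TSV path.
#' @export
write_importances <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
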