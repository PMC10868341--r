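# Internal helpers: seeded evaluation and seed derivation.
#
# All randomness in the package flows from a user-supplied root seed through
# derive_seed(), and every random draw happens inside with_seed() so the
# caller's .Random.seed is never disturbed.

# Evaluate `expr` under `seed`, restoring the global RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Deterministic seed derivation: mixes a root seed with up to three stream
# indices (layer, classifier, purpose). Result is in [1, 2^31 - 2] so it is
# always a valid argument to set.seed().
derive_seed <- function(root, a = 0L, b = 0L, c = 0L) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(root) %% m)
  for (k in c(a, b, c)) {
    x <- (x * 48271 + as.numeric(k) * 9973 + 12345) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dc <- function(...) stop(sprintf(...), call. = FALSE)

# Coerce to a plain numeric matrix and check finiteness.
check_matrix <- function(x, what = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop_dc("'%s' must be a numeric matrix (samples in rows)", what)
  x
}

# Align a label vector (named or positional) with a matrix's rows; returns
# integer 0/1 labels in row order.
align_labels <- function(x, y) {
  if (!is.null(names(y)) && !is.null(rownames(x))) {
    missing <- setdiff(rownames(x), names(y))
    if (length(missing))
      stop_dc("labels missing for samples: %s",
              paste(utils::head(missing, 5), collapse = ", "))
    y <- y[rownames(x)]
  }
  if (length(y) != nrow(x))
    stop_dc("label length (%d) does not match sample count (%d)",
            length(y), nrow(x))
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop_dc("labels must be binary 0/1 (1 = positive class)")
  y
}
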