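# Independent brute-force oracles, written with explicit loops and no code
# shared with the package implementation.

# Per-class centroid vectors by looping over every cell.
oracle_centroids <- function(x, y) {
  p <- ncol(x)
  cp <- numeric(p); cn <- numeric(p)
  for (j in seq_len(p)) {
    sp <- 0; np <- 0; sn <- 0; nn <- 0
    for (i in seq_len(nrow(x))) {
      if (y[i] == 1) { sp <- sp + x[i, j]; np <- np + 1 }
      else           { sn <- sn + x[i, j]; nn <- nn + 1 }
    }
    cp[j] <- sp / np; cn[j] <- sn / nn
  }
  list(pos = cp, neg = cn)
}

oracle_euclid <- function(a, b) {
  s <- 0
  for (j in seq_along(a)) s <- s + (a[j] - b[j])^2
  sqrt(s)
}

# Signed nearest-centroid score: distance to the negative centroid minus
# distance to the positive one.
oracle_ncc_scores <- function(x, cp, cn) {
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x)))
    out[i] <- oracle_euclid(x[i, ], cn) - oracle_euclid(x[i, ], cp)
  out
}

# Argmin-distance class assignment; equidistant samples go to class 0.
oracle_ncc_labels <- function(x, cp, cn) {
  out <- integer(nrow(x))
  for (i in seq_len(nrow(x))) {
    dp <- oracle_euclid(x[i, ], cp)
    dn <- oracle_euclid(x[i, ], cn)
    out[i] <- if (dp < dn) 1L else 0L
  }
  out
}

# Textbook metric formulas from raw confusion counts.
oracle_mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}
oracle_accuracy <- function(tp, fp, tn, fn) (tp + tn) / (tp + fp + tn + fn)
oracle_f1 <- function(tp, fp, tn, fn) {
  prec_den <- tp + fp; rec_den <- tp + fn
  if (tp == 0) return(0)
  prec <- tp / prec_den; rec <- tp / rec_den
  2 * prec * rec / (prec + rec)
}

# All-pairs AUC with ties counted one half.
oracle_auc <- function(y, s) {
  pos <- which(y == 1); neg <- which(y == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (s[i] > s[j]) tot <- tot + 1
    else if (s[i] == s[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# Small labelled Gaussian test matrix with class separation `delta` on all
# features.
make_blobs <- function(n_pos, n_neg, p, delta, seed) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_pos * p, mean = delta), n_pos),
             matrix(rnorm(n_neg * p, mean = 0), n_neg))
  rownames(x) <- paste0("s", seq_len(n_pos + n_neg))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = rep(c(1L, 0L), c(n_pos, n_neg)))
}
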