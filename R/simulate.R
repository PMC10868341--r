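#' Simulate omics-like classification data with planted signal
#'
#' Generates a samples-by-features Gaussian matrix in which a known subset
#' of "informative" features is mean-shifted in the positive class, plus an
#' independent batch-shifted cohort drawn from the same law — the structure
#' needed to exercise feature scanning, out-of-bag pruning, cascading and
#' cross-cohort validation with full ground truth and no downloads.
#'
#' The generative law: every feature is Normal(0, `noise_sd`); informative
#' features additionally receive a mean shift of `effect_size` (in sd units)
#' in positive samples, and may share an equicorrelated latent factor
#' (`block_correlation`). The independent cohort is drawn from the same law
#' and then a location shift of `batch_shift` is added to a random half of
#' the features, emulating the source inconsistencies seen between cohorts
#' (e.g. a discovery cohort versus an external validation cohort). Feature
#' order is randomized so informative features are scattered across columns;
#' contiguous-window scanning therefore cannot trivially capture them.
#'
#' @param n_samples number of training samples (default 200).
#' @param n_features number of features (default 2000).
#' @param n_informative number of planted informative features (default 50).
#' @param effect_size class mean shift on informative features, in sd units
#'   (default 1.0).
#' @param imbalance positive:negative ratio as a length-2 numeric, default
#'   `c(1, 3)` (25\% positives).
#' @param batch_shift location shift applied to a random half of the
#'   features of the independent cohort (default 0.5).
#' @param noise_sd feature standard deviation (default 1).
#' @param block_correlation equicorrelation among informative features in
#'   \[0, 1) (default 0.2).
#' @param n_independent size of the independent cohort (default
#'   `n_samples`).
#' @param heavy_tails if `TRUE`, noise is drawn from a t(5) distribution
#'   (scaled to sd `noise_sd`) instead of a Gaussian, for robustness checks.
#' @param seed integer seed; the whole output is reproducible from it.
#' @return A list of class `"sim_omics"`:
#' \describe{
#'   \item{x, y}{training matrix (rownames `s1..`, colnames `f1..`) and 0/1
#'     labels named by sample.}
#'   \item{x_independent, y_independent}{the batch-shifted cohort.}
#'   \item{informative}{character names of the planted features.}
#'   \item{shifted_features}{names of the batch-shifted features.}
#'   \item{scenario}{the parameter list.}
#' }
#' @examples
#' sim <- simulate_omics(n_samples = 60, n_features = 100,
#'                       n_informative = 10, seed = 1)
#' table(sim$y)
#' @export
simulate_omics <- function(n_samples = 200, n_features = 2000,
                           n_informative = 50, effect_size = 1.0,
                           imbalance = c(1, 3), batch_shift = 0.5,
                           noise_sd = 1, block_correlation = 0.2,
                           n_independent = n_samples,
                           heavy_tails = FALSE, seed = 1) {
  if (n_informative > n_features)
    stop_dc("n_informative (%d) exceeds n_features (%d)",
            n_informative, n_features)
  if (noise_sd <= 0) stop_dc("noise_sd must be > 0")
  if (block_correlation < 0 || block_correlation >= 1)
    stop_dc("block_correlation must be in [0, 1)")
  n_pos <- round(n_samples * imbalance[1] / sum(imbalance))
  n_neg <- n_samples - n_pos
  if (n_pos < 1 || n_neg < 1)
    stop_dc("imbalance %s:%s yields an empty class at n = %d",
            imbalance[1], imbalance[2], n_samples)

  scenario <- list(n_samples = n_samples, n_features = n_features,
                   n_informative = n_informative, effect_size = effect_size,
                   imbalance = imbalance, batch_shift = batch_shift,
                   noise_sd = noise_sd, block_correlation = block_correlation,
                   n_independent = n_independent, heavy_tails = heavy_tails,
                   seed = seed)

  rnoise <- function(n) {
    if (heavy_tails) stats::rt(n, df = 5) / sqrt(5 / 3) * noise_sd
    else stats::rnorm(n, sd = noise_sd)
  }
  draw_cohort <- function(n, y) {
    x <- matrix(rnoise(n * n_features), nrow = n)
    if (block_correlation > 0 && n_informative > 1) {
      ## equicorrelated block: x_j = sqrt(rho) z + sqrt(1-rho) e_j
      z <- rnoise(n)
      rho <- block_correlation
      x[, seq_len(n_informative)] <-
        sqrt(rho) * z + sqrt(1 - rho) * x[, seq_len(n_informative)]
    }
    shift <- effect_size * noise_sd
    x[y == 1L, seq_len(n_informative)] <-
      x[y == 1L, seq_len(n_informative), drop = FALSE] + shift
    x
  }

  out <- with_seed(seed, {
    y <- sample(c(rep(1L, n_pos), rep(0L, n_neg)))
    n_pos_ind <- max(1L, round(n_independent * imbalance[1] / sum(imbalance)))
    y_ind <- sample(c(rep(1L, n_pos_ind),
                      rep(0L, n_independent - n_pos_ind)))
    x <- draw_cohort(n_samples, y)
    x_ind <- draw_cohort(n_independent, y_ind)
    ## scatter informative features across the columns
    perm <- sample.int(n_features)
    x <- x[, perm, drop = FALSE]
    x_ind <- x_ind[, perm, drop = FALSE]
    informative_idx <- match(seq_len(n_informative), perm)
    ## batch shift on a random half of features of the independent cohort
    shifted <- sample.int(n_features, n_features %/% 2)
    x_ind[, shifted] <- x_ind[, shifted] + batch_shift * noise_sd
    list(x = x, y = y, x_ind = x_ind, y_ind = y_ind,
         informative_idx = informative_idx, shifted = shifted)
  })

  fn <- paste0("f", seq_len(n_features))
  dimnames(out$x) <- list(paste0("s", seq_len(n_samples)), fn)
  dimnames(out$x_ind) <- list(paste0("v", seq_len(n_independent)), fn)
  names(out$y) <- rownames(out$x)
  names(out$y_ind) <- rownames(out$x_ind)

  structure(list(x = out$x, y = out$y,
                 x_independent = out$x_ind, y_independent = out$y_ind,
                 informative = fn[out$informative_idx],
                 shifted_features = fn[sort(out$shifted)],
                 scenario = scenario),
            class = "sim_omics")
}

#' @export
print.sim_omics <- function(x, ...) {
  cat(sprintf(paste0("Synthetic omics scenario: %d x %d (train), %d x %d",
                     " (independent)\n"),
              nrow(x$x), ncol(x$x), nrow(x$x_independent),
              ncol(x$x_independent)))
  cat(sprintf("  %d informative features, effect %.2f sd, positives %d/%d\n",
              length(x$informative), x$scenario$effect_size,
              sum(x$y == 1L), length(x$y)))
  if (!is.null(x$x2))
    cat(sprintf("  paired secondary matrix: %d features\n", ncol(x$x2)))
  invisible(x)
}

#' Simulate paired multi-omics data
#'
#' Extends [simulate_omics()] with a paired secondary matrix (e.g. DNA
#' methylation alongside gene expression): the same samples measured on a
#' second feature space with its own informative set, a configurable
#' fraction of which tracks the same latent class signal as the primary
#' matrix.
#'
#' @inheritParams simulate_omics
#' @param n_features_secondary number of secondary features (default 1000).
#' @param n_informative_secondary informative features in the secondary
#'   matrix (default `n_informative`).
#' @param shared_signal_fraction fraction of secondary informative features
#'   carrying the class signal (default 1); the remainder are noise-only.
#' @param ... passed to [simulate_omics()].
#' @return A `"sim_omics"` object with extra fields `x2`,
#'   `x2_independent` and `informative_secondary`.
#' @export
simulate_multiomics <- function(n_features_secondary = 1000,
                                n_informative_secondary = NULL,
                                shared_signal_fraction = 1,
                                effect_size = 1.0, noise_sd = 1,
                                seed = 1, ...) {
  if (shared_signal_fraction < 0 || shared_signal_fraction > 1)
    stop_dc("shared_signal_fraction must be in [0, 1]")
  sim <- simulate_omics(effect_size = effect_size, noise_sd = noise_sd,
                        seed = seed, ...)
  n_inf2 <- n_informative_secondary %||% sim$scenario$n_informative
  if (n_inf2 > n_features_secondary)
    stop_dc("n_informative_secondary exceeds n_features_secondary")
  n_shared <- round(shared_signal_fraction * n_inf2)

  out <- with_seed(derive_seed(seed, 101), {
    draw <- function(n, y) {
      x2 <- matrix(stats::rnorm(n * n_features_secondary, sd = noise_sd),
                   nrow = n)
      if (n_shared > 0) {
        shift <- effect_size * noise_sd
        x2[y == 1L, seq_len(n_shared)] <-
          x2[y == 1L, seq_len(n_shared), drop = FALSE] + shift
      }
      x2
    }
    x2 <- draw(nrow(sim$x), sim$y)
    x2_ind <- draw(nrow(sim$x_independent), sim$y_independent)
    perm <- sample.int(n_features_secondary)  # same scatter for both cohorts
    list(x2 = x2[, perm, drop = FALSE],
         x2_ind = x2_ind[, perm, drop = FALSE],
         informative_idx = match(seq_len(n_inf2), perm))
  })

  fn2 <- paste0("m", seq_len(n_features_secondary))
  dimnames(out$x2) <- list(rownames(sim$x), fn2)
  dimnames(out$x2_ind) <- list(rownames(sim$x_independent), fn2)
  sim$x2 <- out$x2
  sim$x2_independent <- out$x2_ind
  sim$informative_secondary <- fn2[out$informative_idx]
  sim$scenario$n_features_secondary <- n_features_secondary
  sim$scenario$shared_signal_fraction <- shared_signal_fraction
  sim
}
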