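test_that("scenarios build the requested shapes, labels and truth", {
  sim <- simulate_omics(n_samples = 200, n_features = 2000,
                        n_informative = 50, effect_size = 1.0,
                        imbalance = c(1, 3), seed = 7)
  expect_equal(dim(sim$x), c(200, 2000))
  expect_equal(sum(sim$y == 1L), 50)
  expect_equal(sum(sim$y == 0L), 150)
  expect_length(sim$informative, 50)
  expect_true(all(sim$informative %in% colnames(sim$x)))
  expect_equal(colnames(sim$x_independent), colnames(sim$x))
  expect_error(simulate_omics(n_samples = 3, imbalance = c(1, 30)),
               "empty class")
  expect_error(simulate_omics(n_features = 10, n_informative = 20),
               "exceeds")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- simulate_omics(n_samples = 50, n_features = 200, seed = 3,
                      n_informative = 10)
  b <- simulate_omics(n_samples = 50, n_features = 200, seed = 3,
                      n_informative = 10)
  expect_identical(a$x, b$x)
  expect_identical(a$x_independent, b$x_independent)
  expect_identical(a$informative, b$informative)
  c <- simulate_omics(n_samples = 50, n_features = 200, seed = 4,
                      n_informative = 10)
  expect_false(identical(a$x, c$x))
})

test_that("planted effect sizes are recovered empirically", {
  sim <- simulate_omics(n_samples = 500, n_features = 400,
                        n_informative = 40, effect_size = 1.0,
                        block_correlation = 0, seed = 17)
  n1 <- sum(sim$y == 1); n0 <- sum(sim$y == 0)
  diffs <- colMeans(sim$x[sim$y == 1, sim$informative]) -
    colMeans(sim$x[sim$y == 0, sim$informative])
  se_mean <- sqrt(1 / n1 + 1 / n0) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 1.0), 3 * se_mean)
})

test_that("non-informative features carry no class association", {
  ## global null across 10 seeds: no noise feature survives Bonferroni
  worst_p <- vapply(1:10, function(s) {
    sim <- simulate_omics(n_samples = 100, n_features = 300,
                          n_informative = 20, effect_size = 1.0, seed = s)
    noise <- setdiff(colnames(sim$x), sim$informative)
    pv <- vapply(noise, function(f)
      stats::t.test(sim$x[sim$y == 1, f], sim$x[sim$y == 0, f])$p.value, 0)
    min(pv) * length(pv)  # Bonferroni-adjusted minimum
  }, 0)
  expect_gt(min(worst_p) * 10, 0.01)  # adjust across seeds too
})

test_that("a zero effect size leaves the classifier at chance", {
  vals <- vapply(1:10, function(s) {
    sim <- simulate_omics(n_samples = 100, n_features = 300,
                          n_informative = 20, effect_size = 0, seed = s)
    repeated_cv(sim$x, sim$y, ncc_learner(), k = 5, repeats = 1,
                seed = s)$aggregate$mean["mcc"]
  }, 0)
  expect_lt(abs(mean(vals)), 0.15)
})

test_that("paired multi-omics output shares samples and plants shared signal", {
  sim <- simulate_multiomics(n_samples = 150, n_features = 200,
                             n_informative = 20, n_features_secondary = 120,
                             shared_signal_fraction = 1, effect_size = 1.0,
                             seed = 19)
  expect_equal(rownames(sim$x2), rownames(sim$x))
  expect_equal(dim(sim$x2), c(150, 120))
  expect_length(sim$informative_secondary, 20)
  ## every secondary informative feature tracks the class signal
  tstats <- vapply(sim$informative_secondary, function(f)
    unname(stats::t.test(sim$x2[sim$y == 1, f],
                         sim$x2[sim$y == 0, f])$statistic), 0)
  expect_true(all(tstats > 0))
  expect_gt(mean(tstats), 3)
  expect_error(simulate_multiomics(shared_signal_fraction = 2), "0, 1")
})

test_that("fusing a secondary matrix does not hurt the cascade", {
  deltas <- vapply(1:4, function(s) {
    sim <- simulate_multiomics(n_samples = 100, n_features = 300,
                               n_informative = 20,
                               n_features_secondary = 200,
                               effect_size = 1.2, seed = s)
    cfg <- list(n_feature_sets = 50, set_size_min = 10, set_size_max = 50)
    fuse <- do.call(cascade_learner, cfg)
    fuse$fit <- local({
      x2 <- sim$x2
      function(x, y, seed) deep_centroid(x, y,
                                         x2 = x2[rownames(x), , drop = FALSE],
                                         config = do.call(dc_config, cfg),
                                         seed = seed)
    })
    fuse$predict <- local({
      x2 <- rbind(sim$x2, sim$x2_independent)
      function(object, x) {
        p <- predict(object, x, x2[rownames(x), , drop = FALSE])
        data.frame(score = p$probability_positive, label = p$predicted_label)
      }
    })
    single <- do.call(cascade_learner, cfg)
    f <- repeated_cv(sim$x, sim$y, fuse, k = 4, repeats = 1, seed = s)
    g <- repeated_cv(sim$x, sim$y, single, k = 4, repeats = 1, seed = s)
    f$aggregate$mean["mcc"] - g$aggregate$mean["mcc"]
  }, 0)
  expect_gte(mean(deltas), -0.05)
})
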