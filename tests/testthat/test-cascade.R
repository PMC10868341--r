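small_sim <- function(seed, effect = 1.2)
  simulate_omics(n_samples = 100, n_features = 400, n_informative = 30,
                 effect_size = effect, seed = seed)

test_that("z-scoring uses population sd and training statistics only", {
  zs <- zscore_fit(cbind(a = c(0, 2), b = c(3, 3)))
  expect_equal(unname(zs$x[, 1]), c(-1, 1))   # population sd = 1
  expect_equal(unname(zs$x[, 2]), c(0, 0))    # constant column maps to 0

  x <- matrix(rnorm(50 * 4, mean = 3, sd = 2), 50)
  st <- zscore_fit(x)
  expect_equal(unname(colMeans(st$x)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(sweep(st$x, 2, colMeans(st$x))^2))),
               rep(1, 4), tolerance = 1e-12)
  ## a held-out singleton is transformed with the training stats, not its own
  x_new <- matrix(c(10, 20, 30, 40), 1)
  expect_equal(zscore_apply(st, x_new),
               (x_new - rep(st$mean, each = 1)) %*% diag(1 / st$sd),
               tolerance = 1e-12)
  expect_error(zscore_fit(matrix(1, 1, 3)), ">= 2")
})

test_that("balanced resampling allocates draws by the sampling coefficient", {
  y <- rep(c(1L, 0L), c(30, 70))
  sp <- resample_balanced(y, coefficient = 0.65, seed = 1)
  expect_length(sp$train_idx, 100)
  expect_equal(sum(y[sp$train_idx] == 1L), 65)  # minority gets 65 draws
  expect_equal(sum(y[sp$train_idx] == 0L), 35)

  y_bal <- rep(c(1L, 0L), 50)
  sp_bal <- resample_balanced(y_bal, coefficient = 0.5, seed = 2)
  expect_equal(sum(y_bal[sp_bal$train_idx] == 1L), 50)

  ## anchoring the coefficient to the positive class instead
  y_maj_pos <- rep(c(1L, 0L), c(70, 30))
  sp_pos <- resample_balanced(y_maj_pos, 0.65, seed = 3,
                              coefficient_class = "positive")
  expect_equal(sum(y_maj_pos[sp_pos$train_idx] == 1L), 65)

  expect_identical(resample_balanced(y, seed = 9),
                   resample_balanced(y, seed = 9))
  expect_error(resample_balanced(rep(1L, 10)), "both classes")
  expect_error(resample_balanced(y, coefficient = 1.2), "between 0 and 1")
})

test_that("out-of-bag indices never appear in the training multiset", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(10:60, 1)
    y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    sp <- resample_balanced(y, coefficient = runif(1, 0.35, 0.8),
                            seed = sample.int(1e6, 1))
    expect_length(intersect(sp$oob_idx, sp$train_idx), 0)
    expect_gt(length(sp$oob_idx), 0)
    expect_setequal(union(sp$oob_idx, unique(sp$train_idx)), seq_len(n))
  }
})

test_that("layer training prunes by oob MCC and survives planted signal", {
  sim <- small_sim(5)
  z <- zscore_fit(sim$x)$x
  plan <- random_scan(ncol(z), 60, 10, 60, seed = 5)
  cfg <- dc_config(n_feature_sets = 60)
  layer <- train_layer(z, sim$y, plan$feature_sets, cfg, seed = 5)
  expect_gt(length(layer$classifiers), 0)
  expect_gt(layer$val_mcc, 0)
  expect_equal(layer$n_trained, 60)
  expect_equal(layer$n_pruned + length(layer$classifiers), layer$n_trained)
  for (cl in layer$classifiers) expect_gt(cl$val_mcc, cfg$prune_threshold)

  ## MCC >= -1 always, so a threshold of -1 can prune nothing
  loose <- train_layer(z, sim$y, plan$feature_sets,
                       dc_config(n_feature_sets = 60, prune_threshold = -1),
                       seed = 5)
  expect_equal(loose$n_pruned, 0)
})

test_that("permuted labels cause heavy pruning at the default threshold", {
  frac <- vapply(1:10, function(s) {
    sim <- small_sim(s)
    y_perm <- { set.seed(s + 500); sample(sim$y) }
    z <- zscore_fit(sim$x)$x
    plan <- random_scan(ncol(z), 50, 10, 60, seed = s)
    layer <- train_layer(z, y_perm, plan$feature_sets,
                         dc_config(n_feature_sets = 50), seed = s)
    layer$n_pruned / layer$n_trained
  }, 0)
  expect_gte(mean(frac), 0.5)
})

test_that("feature augmentation concatenates scores then re-injected columns", {
  sim <- small_sim(7)
  z <- zscore_fit(sim$x)$x
  plan <- random_scan(ncol(z), 30, 10, 40, seed = 7)
  cfg <- dc_config(n_feature_sets = 30)
  layer <- train_layer(z, sim$y, plan$feature_sets, cfg, seed = 7)
  n_surv <- length(layer$classifiers)

  reinj <- z[, 1:100]
  aug <- augment_features(layer, z, reinj, cfg)
  expect_equal(ncol(aug), n_surv + 100)
  expect_equal(aug[, (n_surv + 1):(n_surv + 100)], unname(reinj),
               ignore_attr = TRUE)

  bare <- augment_features(layer, z, NULL, cfg)
  expect_equal(ncol(bare), n_surv)
  expect_identical(augment_features(layer, z, reinj, cfg), aug)

  ## score columns follow the classifiers' set_id order
  expect_equal(aug[, 1],
               score_centroid(layer$classifiers[[1]]$state,
                              z[, layer$classifiers[[1]]$set]),
               ignore_attr = TRUE)
  ## two distance columns per classifier in "distances" mode
  cfg2 <- dc_config(n_feature_sets = 30, augment_mode = "distances")
  expect_equal(ncol(augment_features(layer, z, NULL, cfg2)), 2 * n_surv)
})

test_that("the cascade terminates, records its stop reason and is reproducible", {
  sim <- small_sim(11)
  fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 60, seed = 4)
  expect_s3_class(fit, "deep_centroid")
  expect_lte(length(fit$layers), fit$config$max_layers)
  expect_true(fit$stop_reason %in% c("no_improvement", "max_layers"))
  ## patience 0: retained layer oob MCC is strictly increasing
  expect_true(all(diff(fit$layer_vals) > 0))

  fit2 <- deep_centroid(sim$x, sim$y, n_feature_sets = 60, seed = 4)
  expect_equal(length(fit2$layers), length(fit$layers))
  expect_identical(vapply(fit2$layers, function(l) length(l$classifiers), 0L),
                   vapply(fit$layers, function(l) length(l$classifiers), 0L))
  expect_identical(predict(fit2, sim$x_independent),
                   predict(fit, sim$x_independent))

  capped <- deep_centroid(sim$x, sim$y, n_feature_sets = 40, max_layers = 1,
                          seed = 4)
  expect_length(capped$layers, 1)
  expect_equal(capped$stop_reason, "max_layers")
})

test_that("no classifier is ever validated on its own training samples", {
  sim <- small_sim(13)
  fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 50, seed = 13)
  for (layer in fit$layers) {
    for (cl in layer$classifiers) {
      expect_gt(cl$val_mcc, fit$config$prune_threshold)
      expect_length(intersect(cl$split$oob_idx, cl$split$train_idx), 0)
    }
  }
})

test_that("multi-omics fusion works in both concatenation and re-injection modes", {
  sim <- simulate_multiomics(n_samples = 100, n_features = 300,
                             n_informative = 25, effect_size = 1.2,
                             n_features_secondary = 200, seed = 21)
  for (mode in c("concatenate", "reinject")) {
    fit <- deep_centroid(sim$x, sim$y, x2 = sim$x2, fusion = mode,
                         n_feature_sets = 50, seed = 2)
    pred <- predict(fit, sim$x_independent, sim$x2_independent)
    expect_equal(nrow(pred), nrow(sim$x_independent))
    expect_gt(mcc(truth = sim$y_independent, pred = pred$predicted_label), 0)
    expect_error(predict(fit, sim$x_independent), "newdata2")
  }
  ## mismatched feature names are a hard error
  expect_error(deep_centroid(sim$x, sim$y, x2 = sim$x), "unique")
})

test_that("the cascade accepts labels by sample name and rejects tiny data", {
  b <- make_blobs(20, 20, 50, delta = 1, seed = 31)
  y_shuffled <- b$y
  names(y_shuffled) <- rownames(b$x)
  y_shuffled <- y_shuffled[sample(names(y_shuffled))]
  fit1 <- deep_centroid(b$x, y_shuffled, n_feature_sets = 20,
                        set_size_min = 5, set_size_max = 20, seed = 1)
  fit2 <- deep_centroid(b$x, b$y, n_feature_sets = 20,
                        set_size_min = 5, set_size_max = 20, seed = 1)
  expect_identical(predict(fit1, b$x), predict(fit2, b$x))
  expect_error(deep_centroid(b$x[1:3, ], b$y[1:3], n_feature_sets = 5),
               ">= 2 per class")
})
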