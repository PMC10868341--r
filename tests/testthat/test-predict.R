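# Build a minimal one-layer model by hand so vote arithmetic can be checked
# exactly: each classifier watches one feature and votes positive iff its
# (already standardized) value is > 0.
make_vote_model <- function(n_voters = 3, p = 3) {
  mk_state <- function() structure(
    list(centroid_pos = 1, centroid_neg = -1,
         distance = "euclidean", n_features = 1L),
    class = "centroid_model")
  classifiers <- lapply(seq_len(n_voters), function(i)
    list(set = i, set_id = i, state = mk_state(), val_mcc = 0.5,
         split = list(train_idx = 1:2, oob_idx = 3:4)))
  layer <- structure(list(classifiers = classifiers, val_mcc = 0.5,
                          n_trained = n_voters, n_pruned = 0L,
                          layer_index = 1L),
                     class = "cascade_layer")
  plan <- random_scan(p, n_sets = n_voters, size_min = 1, size_max = 1,
                      seed = 1)
  structure(list(layers = list(layer), layer_vals = 0.5,
                 scan_plan = plan, scan_plan2 = NULL,
                 config = dc_config(), stop_reason = "max_layers",
                 norm = list(mean = rep(0, p), sd = rep(1, p)),
                 norm2 = NULL,
                 feature_names = paste0("f", seq_len(p)),
                 feature_names2 = NULL, concat_names = NULL,
                 reinject_idx = integer(0), reinject_idx2 = integer(0),
                 n_samples = 4L, call = NULL),
            class = "deep_centroid")
}

test_that("majority voting turns votes into probabilities and labels", {
  m <- make_vote_model()
  x <- rbind(c(1, 1, -1),    # votes (1,1,0) -> prob 2/3, label 1
             c(-1, -1, -1),  # votes (0,0,0) -> prob 0, label 0
             c(1, 1, 1))     # prob 1
  colnames(x) <- paste0("f", 1:3)
  pred <- predict(m, x)
  expect_equal(pred$probability_positive, c(2 / 3, 0, 1))
  expect_equal(pred$predicted_label, c(1L, 0L, 1L))
  expect_equal(attr(pred, "n_voters"), 3)

  ## an exact 50/50 vote split is labelled negative
  m2 <- make_vote_model(n_voters = 4, p = 4)
  x2 <- matrix(c(1, 1, -1, -1), 1, dimnames = list(NULL, paste0("f", 1:4)))
  p2 <- predict(m2, x2)
  expect_equal(p2$probability_positive, 0.5)
  expect_equal(p2$predicted_label, 0L)
})

test_that("vote fractions are always integer vote counts", {
  sim <- simulate_omics(n_samples = 80, n_features = 300, n_informative = 25,
                        effect_size = 1.2, seed = 6)
  fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 40, seed = 6)
  pred <- predict(fit, sim$x_independent)
  nv <- attr(pred, "n_voters")
  expect_equal(nv, length(fit$layers[[length(fit$layers)]]$classifiers))
  counts <- pred$probability_positive * nv
  expect_equal(counts, round(counts), tolerance = 1e-9)
  expect_equal(pred$predicted_label,
               as.integer(pred$probability_positive > 0.5))
})

test_that("shuffling sample order permutes predictions identically", {
  sim <- simulate_omics(n_samples = 80, n_features = 300, n_informative = 25,
                        effect_size = 1.2, seed = 8)
  fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 40, seed = 8)
  x_new <- sim$x_independent
  set.seed(1); perm <- sample.int(nrow(x_new))
  a <- predict(fit, x_new)
  b <- predict(fit, x_new[perm, ])
  expect_equal(b$probability_positive, a$probability_positive[perm])
  expect_equal(b$sample_id, a$sample_id[perm])
})

test_that("a well-separated training set is recovered almost perfectly", {
  vals <- vapply(1:5, function(s) {
    sim <- simulate_omics(n_samples = 100, n_features = 400,
                          n_informative = 40, effect_size = 2.5, seed = s)
    fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 60, seed = s)
    pred <- predict(fit, sim$x)
    mcc(truth = sim$y, pred = pred$predicted_label)
  }, 0)
  expect_true(all(vals >= 0.95))
})

test_that("prediction demands every required feature by name", {
  sim <- simulate_omics(n_samples = 60, n_features = 200, n_informative = 20,
                        effect_size = 1.5, seed = 9)
  fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 30, seed = 9)
  expect_error(predict(fit, sim$x_independent[, -(1:3)]), "f1")
})

test_that("feature importance averages the oob MCC of containing survivors", {
  m <- make_vote_model()
  m$layers[[1]]$classifiers[[1]]$val_mcc <- 0.4
  m$layers[[1]]$classifiers[[1]]$set <- 1L
  m$layers[[1]]$classifiers[[2]]$val_mcc <- 0.2
  m$layers[[1]]$classifiers[[2]]$set <- c(1L, 2L)
  m$layers[[1]]$classifiers[[3]]$val_mcc <- 0.6
  m$layers[[1]]$classifiers[[3]]$set <- 2L
  tab <- rank_important_features(m, 10)
  ## f3 is in no survivor and must be absent
  expect_setequal(tab$feature_name, c("f1", "f2"))
  expect_equal(tab$importance[tab$feature_name == "f1"], (0.4 + 0.2) / 2)
  expect_equal(tab$importance[tab$feature_name == "f2"], (0.2 + 0.6) / 2)
  expect_equal(tab$n_classifiers_containing[tab$feature_name == "f2"], 2)
  expect_equal(tab$feature_name[1], "f2")  # sorted by importance
  expect_error(rank_important_features(m, 0), "top_k")
})

test_that("importance ranking is deterministic for a fitted model", {
  sim <- simulate_omics(n_samples = 80, n_features = 300, n_informative = 25,
                        effect_size = 1.2, seed = 10)
  fit <- deep_centroid(sim$x, sim$y, n_feature_sets = 40, seed = 10)
  expect_identical(rank_important_features(fit, 20),
                   rank_important_features(fit, 20))
})
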