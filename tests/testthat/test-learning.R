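test_that("a single candidate is returned regardless of its score", {
  tab <- random_table(12, 3, seed = 1)
  labels <- rep(c("active", "inactive"), 6)
  only <- model_spec("knn", k = 1)
  out <- loo_select(tab, labels, list(only))
  expect_identical(out$best, only)
  expect_equal(nrow(out$metrics), 1)
})

test_that("LOO confusion counts sum to N for every candidate", {
  tab <- random_table(14, 4, seed = 2)
  labels <- c(rep("active", 5), rep("inactive", 9))
  out <- loo_select(tab, labels, default_search_space(seed = 1))
  sums <- with(out$metrics, tp + tn + fp + fn)
  expect_true(all(sums == 14))
})

test_that("a noise-free planted rule gives 1-NN a perfect LOO MCC", {
  spec <- synthetic_spec(60, 20, 0.5, n_informative = 5, effect_size = 4,
                         noise_sd = 0.2, label_flip_rate = 0, seed = 4)
  gen <- gen_qsar_dataset(spec)
  out <- loo_select(gen$table, gen$dataset$label, list(model_spec("knn", k = 1)))
  expect_equal(out$metrics$mcc, 1)
  # independent brute-force 1-NN oracle agrees on every LOO call
  oracle <- brute_force_1nn_loo(gen$table, gen$dataset$label)
  pred <- orscreen:::loo_predict(gen$table, gen$dataset$label, model_spec("knn", k = 1))
  expect_identical(pred$predicted, oracle)
})

test_that("permuted labels give near-zero best LOO MCC on average", {
  space <- list(model_spec("knn", k = 3), model_spec("knn", k = 5),
                model_spec("decision_tree"))
  best <- vapply(1:20, function(s) {
    tab <- random_table(24, 4, seed = 5000 + s)
    set.seed(s)
    labels <- sample(rep(c("active", "inactive"), each = 12))
    out <- loo_select(tab, labels, space)
    max(ifelse(out$metrics$mcc_defined, out$metrics$mcc, 0))
  }, numeric(1))
  expect_lt(abs(mean(best)), 0.15)
})

test_that("knn prediction follows the weighted-neighbour contract", {
  # 1-D training set, k = 3, uniform weights: two of three neighbours active
  tr <- matrix(c(0.0, 0.1, 1.0), ncol = 1, dimnames = list(c("a", "b", "c"), "d"))
  fit <- train_classifier(tr, c("active", "active", "inactive"),
                          model_spec("knn", k = 3, weighting = "uniform"))
  p <- predict(fit, matrix(0.05, 1, 1, dimnames = list("q", "d")))
  expect_equal(p$score, 2 / 3)
  expect_equal(p$predicted, "active")

  # exact tie at score 0.5 resolves to active
  tr2 <- matrix(c(0, 1), ncol = 1, dimnames = list(c("a", "b"), "d"))
  fit2 <- train_classifier(tr2, c("active", "inactive"),
                           model_spec("knn", k = 2, weighting = "uniform"))
  p2 <- predict(fit2, matrix(0.5, 1, 1, dimnames = list("q", "d")))
  expect_equal(p2$score, 0.5)
  expect_equal(p2$predicted, "active")

  # k = 1 on a training point returns its own label with score 1
  fit3 <- train_classifier(tr2, c("active", "inactive"), model_spec("knn", k = 1))
  p3 <- predict(fit3, tr2)
  expect_equal(p3$predicted, c("active", "inactive"))
  expect_equal(p3$score, c(1, 0))
})

test_that("inverse-distance weighting lets an exact match dominate", {
  tr <- matrix(c(0, 0.4, 0.5), ncol = 1, dimnames = list(c("a", "b", "c"), "d"))
  fit <- train_classifier(tr, c("active", "inactive", "inactive"),
                          model_spec("knn", k = 3, weighting = "inverse_distance"))
  p <- predict(fit, matrix(0, 1, 1, dimnames = list("q", "d")))
  expect_gt(p$score, 0.999)
})

test_that("training preconditions are enforced", {
  tab <- random_table(6, 2, seed = 3)
  expect_error(train_classifier(tab, rep("active", 6), model_spec("knn", k = 1)),
               "both classes")
  expect_error(train_classifier(tab, rep(c("active", "inactive"), 3),
                                model_spec("knn", k = 7)), "exceeds")
  # inside a LOO loop only N - 1 neighbours exist
  expect_error(loo_select(tab, rep(c("active", "inactive"), 3),
                          list(model_spec("knn", k = 6))), "LOO")
  expect_error(loo_select(tab, rep("active", 6), list(model_spec("knn", k = 1))),
               "both classes")
  expect_error(model_spec("knn", n_trees = 5), "invalid hyperparameter")
})

test_that("stochastic families are deterministic under a fixed seed", {
  set.seed(99)
  tab <- random_table(30, 6, seed = 10)
  labels <- sample(rep(c("active", "inactive"), 15))
  probe <- random_table(10, 6, seed = 11)
  for (fam in list(model_spec("random_forest", n_trees = 50, seed = 7),
                   model_spec("random_tree", seed = 7),
                   model_spec("svc", cost = 1, seed = 7))) {
    p1 <- predict(train_classifier(tab, labels, fam), probe)
    p2 <- predict(train_classifier(tab, labels, fam), probe)
    expect_identical(p1, p2, label = fam$family)
  }
})

test_that("column mismatches and empty queries follow the contract", {
  tab <- random_table(10, 3, seed = 12)
  labels <- rep(c("active", "inactive"), 5)
  fit <- train_classifier(tab, labels, model_spec("knn", k = 3))
  expect_error(predict(fit, tab[, 1:2, drop = FALSE]), "d03")
  empty <- predict(fit, tab[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
})

test_that("model selection is reproducible bit-for-bit under a fixed seed", {
  pre <- receptor_preset("or24", seed = 6)
  pre$spec <- synthetic_spec(30, 12, 0.4, seed = 6) # small grid for speed
  gen <- gen_qsar_dataset(pre$spec)
  norm <- apply_minmax(gen$table, fit_minmax(gen$table))
  space <- default_search_space(seed = 2)
  a <- loo_select(norm, gen$dataset$label, space)
  b <- loo_select(norm, gen$dataset$label, space)
  expect_identical(a$best_index, b$best_index)
  expect_identical(a$metrics, b$metrics)
})
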