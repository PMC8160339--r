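test_that("60:20:20 split has the documented sizes and determinism", {
  ft <- toy_features(n = 684, prevalence = 150 / 684, seed = 30)
  sp <- split_60_20_20(ft, seed = 1)
  expect_equal(lengths(sp), c(train = 410, validation = 137,
                              internal_test = 137))
  expect_identical(sp, split_60_20_20(ft, seed = 1))
  expect_equal(sort(unlist(sp)), 1:684, ignore_attr = TRUE)

  tiny <- toy_features(n = 5, prevalence = 0.4, seed = 31)
  tiny$label <- c(1L, 0L, 0L, 1L, 0L)
  sp5 <- split_60_20_20(tiny, seed = 2)
  expect_equal(unname(lengths(sp5)), c(3, 1, 1))
})

test_that("architecture constraints and enumeration counts hold", {
  expect_error(mlp_architecture(c(5, 20)), "exceeds")
  expect_error(mlp_architecture(c(2, 5)), "n1 >= n2")
  expect_error(mlp_architecture(integer(0)), "hidden layers")
  two_layer <- enumerate_architectures(20, layers = 2)
  expect_length(two_layer, 100)
  expect_true(all(vapply(two_layer, sum, numeric(1)) <= 20))
  one_layer <- enumerate_architectures(20, layers = 1)
  expect_length(one_layer, 20)
  expect_length(enumerate_architectures(1), 1)
  # ordering: total nodes ascending, then fewer layers
  all20 <- enumerate_architectures(20)
  tot <- vapply(all20, sum, numeric(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("every training function solves a separable toy problem", {
  ft <- toy_features(n = 150, informative = feature_names(with_size = FALSE),
                     effect = 6, seed = 32)
  sp <- split_60_20_20(ft, seed = 3)
  it <- ft[sp$internal_test, ]
  for (fun in mlp_registry()) {
    m <- train_mlp(mlp_architecture(4, fun, seed = 1), sp, ft,
                   max_epochs = 200, patience = 25)
    f1 <- score_triple(it$label, predict(m, it))$f1
    expect_gte(f1, 0.999)
    # restore-best contract: stored weights attain the best recorded val F1
    expect_equal(m$best_val_f1, max(m$history$val_f1))
  }
})

test_that("the search returns the architecture an exhaustive oracle picks", {
  ft <- toy_features(n = 120, informative = "magn_f2", effect = 5, seed = 33)
  sp <- split_60_20_20(ft, seed = 4)
  it <- ft[sp$internal_test, ]
  best <- search_architecture("bfgs", ft, sp, max_nodes = 3, beta = 1,
                              seed = 7, max_epochs = 60, patience = 8)
  log <- attr(best, "log")
  # independent retraining of every candidate reproduces the same scores
  ora <- vapply(enumerate_architectures(3), function(nodes) {
    m <- train_mlp(mlp_architecture(nodes, "bfgs", seed = 7), sp, ft,
                   max_epochs = 60, patience = 8)
    score_triple(it$label, predict(m, it))$f1
  }, numeric(1))
  expect_equal(log$internal_test, unname(ora))
  expect_equal(attr(best, "score"), max(ora))
  # max_nodes = 1 has a single candidate
  single <- search_architecture("gd", ft, sp, max_nodes = 1, beta = 1,
                                seed = 7, max_epochs = 20, patience = 5)
  expect_equal(single$nodes, 1L)
})

test_that("function selection is reproducible and registry-closed", {
  ft <- toy_features(n = 120, effect = 4, seed = 34)
  r1 <- select_training_function(ft, registry = c("bfgs", "gdx"),
                                 max_nodes = 2, layers = 1, beta = 1,
                                 seed = 5, max_epochs = 40, patience = 6)
  r2 <- select_training_function(ft, registry = c("bfgs", "gdx"),
                                 max_nodes = 2, layers = 1, beta = 1,
                                 seed = 5, max_epochs = 40, patience = 6)
  expect_true(r1$fun %in% c("bfgs", "gdx"))
  expect_identical(r1$fun, r2$fun)
  expect_identical(r1$arch$nodes, r2$arch$nodes)
  expect_identical(r1$model$theta, r2$model$theta)
  one <- select_training_function(ft, registry = "lm", max_nodes = 2,
                                  layers = 1, beta = 1, seed = 5,
                                  max_epochs = 30, patience = 5)
  expect_equal(one$fun, "lm")
})
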