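test_that("1-NN reproduces its own training labels", {
  ft <- toy_features(n = 80, seed = 5)
  m <- train_classifier(classifier_spec("knn", list(k = 1)), ft, seed = 1)
  expect_equal(evaluate_model(m, ft)$f1, 1)
})

test_that("every family separates well-separated classes", {
  ft <- toy_features(n = 240, informative = c("magn_f3", "tand_f4"),
                     effect = 8, seed = 6)
  ftt <- toy_features(n = 120, informative = c("magn_f3", "tand_f4"),
                      effect = 8, seed = 7)
  for (fam in c("lr", "dt", "nbc", "knn", "svm")) {
    m <- train_classifier(classifier_spec(fam), ft, seed = 2)
    expect_gte(evaluate_model(m, ftt)$f1, 0.95)
  }
})

test_that("the in-package KNN agrees with class::knn where comparable", {
  skip_if_not_installed("class")
  ft <- toy_features(n = 151, prevalence = 0.5, seed = 8)   # near-balanced
  ftt <- toy_features(n = 60, prevalence = 0.5, seed = 9)
  # balanced weights: force uniform_prior off so votes are unweighted
  spec <- classifier_spec("knn", list(k = 5, metric = "euclidean"),
                          uniform_prior = FALSE)
  m <- train_classifier(spec, ft, seed = 1)
  mine <- predict(m, ftt)
  xn_tr <- apply_normalization(m$norm, ft)
  xn_te <- apply_normalization(m$norm, ftt)
  ref <- as.integer(as.character(
    class::knn(xn_tr, xn_te, factor(ft$label), k = 5)))
  # class::knn breaks exact vote ties randomly; compare off-tie rows
  votes <- sapply(seq_len(nrow(xn_te)), function(i) {
    d <- sqrt(colSums((t(xn_tr) - xn_te[i, ])^2))
    sum(ft$label[order(d)[1:5]])
  })
  off_tie <- votes != 2.5
  expect_true(all(mine[off_tie] == ref[off_tie]))
})

test_that("gaussian naive Bayes agrees with e1071 on balanced data", {
  ft <- toy_features(n = 160, prevalence = 0.5, seed = 10)
  ftt <- toy_features(n = 80, prevalence = 0.5, seed = 11)
  spec <- classifier_spec("nbc", list(likelihood = "gaussian"),
                          uniform_prior = FALSE)
  m <- train_classifier(spec, ft, seed = 1)
  xn_tr <- apply_normalization(m$norm, ft)
  xn_te <- apply_normalization(m$norm, ftt)
  ref_fit <- e1071::naiveBayes(xn_tr, factor(ft$label))
  ref <- as.integer(as.character(predict(ref_fit, xn_te)))
  expect_equal(predict(m, ftt), ref)
})

test_that("training refuses single-class data and missing features", {
  ft <- toy_features(n = 40, seed = 12)
  ft$label <- 0L
  expect_error(train_classifier(classifier_spec("knn"), ft), "one class")
  ft2 <- toy_features(n = 40, seed = 12)
  expect_error(train_classifier(classifier_spec("svm"),
                                ft2[, setdiff(names(ft2), "py")]), "py")
})

test_that("grid enumeration is simplest-first and complete", {
  g <- grid_combinations("knn")
  expect_length(g, 14)
  expect_equal(g[[1]]$k, 25)                    # largest k = smoothest first
  expect_equal(g[[1]]$metric, "euclidean")
  expect_equal(g[[length(g)]]$k, 1)
  s <- grid_combinations("svm")
  expect_length(s, 4 + 12)                      # linear x4 + rbf x4x3
  expect_true(all(vapply(s[1:4], function(p) p$kernel == "linear",
                         logical(1))))
  d <- grid_combinations("dt")
  expect_equal(d[[1]]$maxdepth, 2)
  expect_equal(d[[1]]$minbucket, 10)
})

test_that("training is deterministic given the seed", {
  ft <- toy_features(n = 120, seed = 13)
  ftt <- toy_features(n = 60, seed = 14)
  for (fam in c("lr", "dt", "nbc", "knn", "svm")) {
    m1 <- train_classifier(classifier_spec(fam), ft, seed = 3)
    m2 <- train_classifier(classifier_spec(fam), ft, seed = 3)
    expect_identical(predict(m1, ftt), predict(m2, ftt))
  }
})

test_that("uniform priors rebalance a skewed training set", {
  # 8:1 imbalance with weak signal: with uniform priors the minority class
  # must still be predicted a non-trivial fraction of the time
  ft <- toy_features(n = 450, prevalence = 1 / 9, effect = 1.2, seed = 15)
  ftt <- toy_features(n = 200, prevalence = 0.5, effect = 1.2, seed = 16)
  for (fam in c("lr", "nbc", "knn", "svm")) {
    m_u <- train_classifier(classifier_spec(fam), ft, seed = 1)
    rate_u <- mean(predict(m_u, ftt))
    expect_gt(rate_u, 0.2)
  }
})
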