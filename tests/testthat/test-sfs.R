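test_that("fold assignment is stratified, seeded and validated", {
  y <- rep(c(0L, 1L), c(60, 30))
  f1 <- cv_folds(y, 10, seed = 2)
  f2 <- cv_folds(y, 10, seed = 2)
  expect_identical(f1, f2)
  for (k in 1:10) expect_true(all(table(y[f1 == k]) >= 1))
  expect_error(cv_folds(y, 40, seed = 1), "invalid cv")
  expect_error(cv_folds(y, 1, seed = 1), "invalid cv")
})

test_that("an infinite tolerance keeps all 18 features, size always kept", {
  ft <- toy_features(n = 100, seed = 20)
  kept <- backward_sfs("knn", list(k = 5), ft, beta = 1, folds = 4,
                       seed = 1, tol = Inf)
  expect_identical(as.character(kept), feature_names())
  kept2 <- backward_sfs("nbc", list(likelihood = "gaussian"), ft, beta = 1,
                        folds = 4, seed = 1, tol = 1e-4)
  expect_true("size_mm" %in% kept2)
})

test_that("importance is the selection frequency across the grid", {
  ft <- toy_features(n = 120, effect = 5, seed = 21)
  prof <- importance_profile("knn", list(k = c(3L, 5L), metric = "euclidean"),
                             ft, beta = 1, folds = 4, seed = 2)
  expect_true(all(prof$importance >= 0 & prof$importance <= 1))
  expect_equal(unname(prof$importance["size_mm"]), 1)
  # single-combination grid: importance is that run's 0/1 indicator
  prof1 <- importance_profile("knn", list(k = 5L, metric = "euclidean"),
                              ft, beta = 1, folds = 4, seed = 2)
  expect_true(all(prof1$importance %in% c(0, 1)))
  expect_identical(names(which(prof1$importance == 1)),
                   as.character(prof1$retained[[1]]))
})

test_that("threshold subsets have sizes 18/12/9/6 with deterministic ties", {
  ft <- toy_features(n = 100, seed = 22)
  prof <- importance_profile("nbc", list(likelihood = "gaussian"), ft,
                             beta = 1, folds = 4, seed = 3)
  subs <- subsets_from_thresholds(prof)
  expect_equal(unname(vapply(subs, length, integer(1))), c(18, 12, 9, 6))
  expect_true(all(vapply(subs, function(s) "size_mm" %in% s, logical(1))))
  expect_identical(subs$full, feature_names())
  # all-equal importances fall back to canonical order (plus size)
  prof$importance[] <- 0.5
  prof$importance["size_mm"] <- 0.5
  subs2 <- subsets_from_thresholds(prof)
  expect_identical(subs2$low,
                   c(feature_names()[1:5], "size_mm"))
})

test_that("hyperparameter optimisation matches an exhaustive oracle", {
  ft <- toy_features(n = 140, effect = 6, seed = 23)
  grid <- list(k = c(9L, 5L, 3L, 1L), metric = "euclidean")
  spec <- optimize_hyperparameters("knn", feature_names(), ft, beta = 1,
                                   folds = 5, seed = 4, grid = grid)
  # independent re-evaluation of every grid point on the same folds
  fold_id <- cv_folds(ft$label, 5, seed = 4)
  ora <- vapply(grid_combinations("knn", grid), function(p)
    cv_fbeta("knn", p, feature_names(), ft, 1, fold_id), numeric(1))
  expect_equal(attr(spec, "cv_fbeta"), max(ora))
  expect_equal(unname(attr(spec, "cv_scores")), unname(ora))
  # a one-point grid returns that point
  one <- optimize_hyperparameters("knn", feature_names(), ft, beta = 1,
                                  folds = 5, seed = 4,
                                  grid = list(k = 7L, metric = "manhattan"))
  expect_equal(one$params$k, 7L)
  # duplicated grid values tie exactly; the earlier (simpler) entry wins
  dup <- optimize_hyperparameters("knn", feature_names(), ft, beta = 1,
                                  folds = 5, seed = 4,
                                  grid = list(k = c(5L, 5L),
                                              metric = "euclidean"))
  expect_equal(dup$params$k, 5L)
  expect_equal(which.max(attr(dup, "cv_scores")), 1L)
})

test_that("bootstrap summary is ordered and degenerates to zero width", {
  # perfectly separable: every round scores 1, so the CI has zero width
  ft <- toy_features(n = 60, informative = feature_names(with_size = FALSE),
                     effect = 50, seed = 24)
  spec <- classifier_spec("knn", list(k = 1))
  bs <- bootstrap_validate(spec, ft, beta = 1, rounds = 40, seed = 5)
  expect_equal(bs$values, rep(1, 40))
  expect_equal(bs$ci_hi - bs$ci_lo, 0)

  ft2 <- toy_features(n = 90, effect = 1.5, seed = 25)
  bs2 <- bootstrap_validate(classifier_spec("knn", list(k = 5)), ft2,
                            beta = 1, rounds = 60, seed = 6)
  expect_lte(bs2$ci_lo, bs2$median)
  expect_lte(bs2$median, bs2$ci_hi)
  expect_length(bs2$values, 60)
  # reproducible
  bs3 <- bootstrap_validate(classifier_spec("knn", list(k = 5)), ft2,
                            beta = 1, rounds = 60, seed = 6)
  expect_identical(bs2$values, bs3$values)
})
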