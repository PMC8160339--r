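#' Stratified cross-validation fold assignment
#'
#' @param y Binary label vector.
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed; the assignment is fixed by it.
#' @return Integer vector of fold ids in `1:folds`.
#' @export
cv_folds <- function(y, folds = 10, seed = 1) {
  y <- as.integer(y)
  if (folds < 2) stop("invalid cv: need >= 2 folds", call. = FALSE)
  if (folds > min(table(factor(y, levels = 0:1))))
    stop("invalid cv: more folds than members of the smaller class",
         call. = FALSE)
  id <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in 0:1) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  id
}

#' Cross-validated F-beta for one family/parameter/feature combination
#'
#' Trains on each fold complement (normalisation refit inside every fold, so
#' no statistics leak from held-out rows), predicts the held-out rows and
#' scores the F-beta of the pooled out-of-fold confusion.
#'
#' @param family Family id.
#' @param params Hyperparameter list.
#' @param features Feature subset.
#' @param train Feature table with `label`.
#' @param beta F-score weighting.
#' @param fold_id Fold assignment from [cv_folds()].
#' @param uniform_prior Passed to [classifier_spec()].
#' @return Scalar CV F-beta.
#' @export
cv_fbeta <- function(family, params, features, train, beta, fold_id,
                     uniform_prior = TRUE) {
  pred <- integer(nrow(train))
  spec <- classifier_spec(family, params, features, uniform_prior)
  for (f in sort(unique(fold_id))) {
    hold <- fold_id == f
    m <- train_classifier(spec, train[!hold, , drop = FALSE], seed = 1)
    pred[hold] <- predict(m, train[hold, , drop = FALSE])
  }
  fbeta_score(confusion_counts(train$label, pred), beta)
}

#' Backward sequential feature selection
#'
#' Multi-pass greedy backward elimination: starting from all features, each
#' pass removes the single feature whose removal most improves the
#' cross-validated F-beta, and stops when no removal improves it by more than
#' `tol`. The fruit-size feature is never removable (it is the agreed
#' correction covariate); the fold assignment is fixed by `seed` so every
#' grid combination sees identical folds.
#'
#' @inheritParams cv_fbeta
#' @param folds Number of CV folds (default 10).
#' @param seed Seed fixing the fold assignment.
#' @param tol Minimum CV improvement to accept a removal (default 1e-4).
#' @param features Starting feature set (default all 18).
#' @return Character vector of retained features (canonical order), with
#'   attribute `cv_fbeta` (the final CV score).
#' @export
backward_sfs <- function(family, params, train, beta = 1, folds = 10,
                         seed = 1, tol = 1e-4,
                         features = feature_names()) {
  fold_id <- cv_folds(train$label, folds, seed)
  current <- features
  score <- cv_fbeta(family, params, current, train, beta, fold_id)
  repeat {
    removable <- setdiff(current, "size_mm")
    if (length(removable) == 0 || length(current) <= 1) break
    trial <- vapply(removable, function(f)
      cv_fbeta(family, params, setdiff(current, f), train, beta, fold_id),
      numeric(1))
    best <- which.max(trial)
    if (trial[best] > score + tol) {
      current <- setdiff(current, removable[best])
      score <- trial[best]
    } else break
  }
  out <- features[features %in% current]
  attr(out, "cv_fbeta") <- score
  out
}

#' Selection-frequency feature importance across a hyperparameter grid
#'
#' Runs [backward_sfs()] once per grid combination; a feature's importance is
#' the fraction of combinations whose retained set contains it. Size is
#' retained by construction, so its importance is always 1.
#'
#' @inheritParams backward_sfs
#' @param grid Hyperparameter grid ([default_grids()] format).
#' @return List of class `importance_profile`: `family`, `beta`,
#'   `importance` (named vector in `[0, 1]`), `retained` (list of per-combo
#'   retained sets).
#' @export
importance_profile <- function(family, grid = default_grids()[[family]],
                               train, beta = 1, folds = 10, seed = 1,
                               tol = 1e-4, features = feature_names()) {
  combos <- grid_combinations(family, grid)
  if (length(combos) == 0) stop("empty hyperparameter grid", call. = FALSE)
  retained <- lapply(combos, function(p)
    backward_sfs(family, p, train, beta, folds, seed, tol, features))
  imp <- vapply(features, function(f)
    mean(vapply(retained, function(r) f %in% r, logical(1))), numeric(1))
  structure(list(family = family, beta = beta, importance = imp,
                 retained = retained),
            class = "importance_profile")
}

#' Feature subsets from numerosity thresholds
#'
#' Builds the four nested working subsets: `full` (all 18 features) and
#' `high`/`medium`/`low` keeping the top 12, 9 and 6 features by importance
#' (about 2/3, 1/2 and 1/3 of 18). Ties break toward the canonical column
#' order; fruit size is always included within the budget.
#'
#' @param profile An [importance_profile()].
#' @param sizes Named integer vector of subset sizes.
#' @return Named list of character vectors (`full`, `high`, `medium`, `low`).
#' @export
subsets_from_thresholds <- function(profile,
                                    sizes = c(full = 18, high = 12,
                                              medium = 9, low = 6)) {
  stopifnot(inherits(profile, "importance_profile"))
  imp <- profile$importance
  feats <- names(imp)
  ord <- feats[order(-imp, seq_along(imp))]
  lapply(sizes, function(k) {
    k <- min(k, length(feats))
    top <- ord[seq_len(k)]
    if (!"size_mm" %in% top && "size_mm" %in% feats)
      top <- c(top[seq_len(k - 1)], "size_mm")
    feats[feats %in% top]
  })
}

#' Grid search of hyperparameters by cross-validated F-beta
#'
#' Evaluates every grid combination on fixed stratified folds and returns the
#' maximiser. Ties break toward the simpler model (the enumeration order of
#' [grid_combinations()] is simplest-first), then grid order.
#'
#' @inheritParams backward_sfs
#' @param grid Hyperparameter grid.
#' @return A [classifier_spec()] with attributes `cv_fbeta` and `cv_scores`.
#' @export
optimize_hyperparameters <- function(family, features = feature_names(),
                                     train, beta = 1, folds = 10, seed = 1,
                                     grid = default_grids()[[family]]) {
  combos <- grid_combinations(family, grid)
  if (length(combos) == 0) stop("empty hyperparameter grid", call. = FALSE)
  fold_id <- cv_folds(train$label, folds, seed)
  scores <- vapply(combos, function(p)
    cv_fbeta(family, p, features, train, beta, fold_id), numeric(1))
  best <- which.max(scores)  # first max = simplest among ties
  spec <- classifier_spec(family, combos[[best]], features)
  attr(spec, "cv_fbeta") <- scores[best]
  attr(spec, "cv_scores") <- scores
  spec
}

#' Out-of-bag bootstrap validation of a classifier spec
#'
#' Each round draws `n` training rows with replacement, trains the spec on
#' the draw and scores F-beta on the out-of-bag rows. Rounds whose draw has a
#' single class or an empty out-of-bag set are redrawn (and counted).
#'
#' @param spec A [classifier_spec()].
#' @param train Feature table with `label`.
#' @param beta F-score weighting.
#' @param rounds Number of bootstrap rounds (default 200; the full-scale
#'   protocol uses 10000).
#' @param seed Integer seed.
#' @return List of class `bootstrap_summary`: `beta`, `rounds`, `values`,
#'   `median`, `ci_lo`, `ci_hi` (2.5/97.5 percentiles), `redraws`.
#' @export
bootstrap_validate <- function(spec, train, beta = 1, rounds = 200,
                               seed = 1) {
  stopifnot(rounds >= 1)
  n <- nrow(train)
  values <- numeric(rounds)
  redraws <- 0L
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(rounds)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        oob <- setdiff(seq_len(n), idx)
        if (length(oob) > 0 &&
            length(unique(train$label[idx])) == 2) break
        redraws <- redraws + 1L
        if (redraws > 1000L * rounds)
          stop("bootstrap cannot draw two-class resamples", call. = FALSE)
      }
      m <- train_classifier(spec, train[idx, , drop = FALSE], seed = 1)
      pred <- predict(m, train[oob, , drop = FALSE])
      values[r] <- fbeta_score(confusion_counts(train$label[oob], pred), beta)
    }
  })
  structure(list(beta = beta, rounds = rounds, values = values,
                 median = stats::median(values),
                 ci_lo = unname(stats::quantile(values, 0.025)),
                 ci_hi = unname(stats::quantile(values, 0.975)),
                 redraws = redraws),
            class = "bootstrap_summary")
}

#' @method print bootstrap_summary
#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("<bootstrap_summary> beta=", x$beta, ", ", x$rounds,
      " rounds: median F=", format(x$median, digits = 3), " [",
      format(x$ci_lo, digits = 3), ", ", format(x$ci_hi, digits = 3),
      "] (", x$redraws, " redraws)\n", sep = "")
  invisible(x)
}
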