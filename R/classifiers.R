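#' Classifier specification
#'
#' Family id, hyperparameters, feature subset and the uniform-prior flag that
#' together define one trainable model. Families: logistic regression
#' (`"lr"`, ridge-penalised), decision tree (`"dt"`), naive Bayes (`"nbc"`,
#' Gaussian or kernel-density likelihoods), K-nearest neighbours (`"knn"`,
#' euclidean or manhattan, inverse-frequency-weighted voting) and support
#' vector machine (`"svm"`, linear or RBF kernel).
#'
#' @param family One of `"lr"`, `"dt"`, `"nbc"`, `"knn"`, `"svm"`.
#' @param params Named list of hyperparameters (see [default_grids()]).
#' @param features Character vector of feature columns to use.
#' @param uniform_prior Treat both class priors as equal (counters the
#'   unripe/ripe training imbalance); default `TRUE`.
#' @return List of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("lr", "dt", "nbc", "knn", "svm"),
                            params = list(), features = feature_names(),
                            uniform_prior = TRUE) {
  family <- match.arg(family)
  defaults <- lapply(default_grids()[[family]], `[[`, 1)
  missing <- setdiff(names(defaults), names(params))
  params <- c(params, defaults[missing])
  structure(list(family = family, params = params, features = features,
                 uniform_prior = isTRUE(uniform_prior)),
            class = "classifier_spec")
}

#' Default hyperparameter grids
#'
#' One named list per family; each element is the vector of candidate values
#' for one hyperparameter, listed from simplest to most complex so that grid
#' order doubles as the tie-break order during optimisation.
#'
#' @return Named list of per-family grids.
#' @export
default_grids <- function() {
  list(
    lr = list(lambda = c(10, 1, 0.1, 0.01)),
    dt = list(maxdepth = 2:10, minbucket = c(10, 5, 1)),
    nbc = list(likelihood = c("gaussian", "kernel")),
    knn = list(k = c(25, 15, 9, 7, 5, 3, 1),
               metric = c("euclidean", "manhattan")),
    svm = list(kernel = c("linear", "rbf"), cost = c(0.1, 1, 10, 100),
               gamma = c("scale", "0.01", "0.1"))
  )
}

#' Enumerate grid combinations for a family, simplest first
#'
#' @param family Family id.
#' @param grid Grid in [default_grids()] format; default the family default.
#' @return List of named parameter lists.
#' @export
grid_combinations <- function(family, grid = default_grids()[[family]]) {
  if (identical(family, "svm")) {
    # linear kernel has no gamma: collapse that axis
    g <- expand.grid(grid[c("kernel", "cost", "gamma")],
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    g <- g[!(g$kernel == "linear" & g$gamma != grid$gamma[1]), , drop = FALSE]
    g <- g[order(match(g$kernel, grid$kernel), g$cost,
                 match(g$gamma, grid$gamma)), , drop = FALSE]
  } else {
    g <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    ord <- do.call(order, lapply(names(grid), function(p)
      match(g[[p]], grid[[p]])))
    g <- g[ord, , drop = FALSE]
  }
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# Uniform-prior case weights: each class contributes half the total mass.
prior_weights <- function(y) {
  n <- length(y); n1 <- sum(y == 1L); n0 <- n - n1
  ifelse(y == 1L, n / (2 * n1), n / (2 * n0))
}

#' Train one ripeness classifier
#'
#' Fits the requested family on the z-score-normalised feature subset
#' (normalisation statistics are learned from these training rows and stored
#' in the model, so new data is always transformed with training statistics).
#' With `uniform_prior` both classes are given equal prior mass regardless of
#' the training imbalance: case weights for LR, native class priors for the
#' tree, equal log-priors for naive Bayes, inverse-frequency-weighted voting
#' for KNN and class weights for the SVM.
#'
#' @param spec A [classifier_spec()].
#' @param train Feature table (needs `label` plus the spec's features).
#' @param seed Integer seed (stored; fitting is deterministic given it).
#' @return Object of class `ripeness_model`.
#' @export
train_classifier <- function(spec, train, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(train$label)
  if (length(unique(y)) < 2)
    stop("invalid training set: only one class present", call. = FALSE)
  missing <- setdiff(spec$features, names(train))
  if (length(missing))
    stop("training table lacks features: ", paste(missing, collapse = ", "),
         call. = FALSE)
  norm <- fit_normalization(train[, spec$features, drop = FALSE])
  xn <- apply_normalization(norm, train)
  p <- spec$params
  w <- if (spec$uniform_prior) prior_weights(y) else rep(1, length(y))
  fit <- withr::with_seed(as.integer(seed), switch(
    spec$family,
    lr = glmnet::glmnet(xn, factor(y, levels = 0:1), family = "binomial",
                        alpha = 0, lambda = p$lambda, weights = w,
                        standardize = FALSE),
    dt = {
      d <- data.frame(.y = factor(y, levels = 0:1), xn, check.names = FALSE)
      prior <- if (spec$uniform_prior) c(0.5, 0.5) else
        as.numeric(table(factor(y, levels = 0:1))) / length(y)
      rpart::rpart(.y ~ ., data = d, method = "class",
                   parms = list(prior = prior),
                   control = rpart::rpart.control(
                     maxdepth = p$maxdepth, minbucket = p$minbucket,
                     minsplit = max(2L, 2L * p$minbucket), cp = 0, xval = 0))
    },
    nbc = fit_nbc(xn, y, likelihood = p$likelihood,
                  uniform_prior = spec$uniform_prior),
    knn = list(x = xn, y = y, k = p$k, metric = p$metric,
               class_w = if (spec$uniform_prior)
                 length(y) / (2 * c(sum(y == 0L), sum(y == 1L)))
               else c(1, 1)),
    svm = {
      gamma <- if (identical(p$gamma, "scale")) 1 / ncol(xn)
               else as.numeric(p$gamma)
      cw <- if (spec$uniform_prior) {
        v <- length(y) / (2 * c(sum(y == 0L), sum(y == 1L)))
        stats::setNames(v, c("0", "1"))
      } else NULL
      e1071::svm(xn, factor(y, levels = 0:1),
                 kernel = if (p$kernel == "rbf") "radial" else "linear",
                 cost = p$cost, gamma = gamma, class.weights = cw,
                 scale = FALSE)
    }))
  structure(list(spec = spec, norm = norm, fit = fit, seed = seed,
                 n_train = length(y)),
            class = "ripeness_model")
}

# Naive Bayes with explicit priors and gaussian or kernel-density likelihoods.
fit_nbc <- function(xn, y, likelihood = "gaussian", uniform_prior = TRUE) {
  classes <- 0:1
  prior <- if (uniform_prior) c(0.5, 0.5) else
    as.numeric(table(factor(y, levels = classes))) / length(y)
  per_class <- lapply(classes, function(cl) {
    xc <- xn[y == cl, , drop = FALSE]
    if (likelihood == "gaussian") {
      list(mean = colMeans(xc), sd = pmax(apply(xc, 2, stats::sd), 1e-9))
    } else {
      lapply(seq_len(ncol(xc)), function(j) {
        d <- stats::density(xc[, j], n = 512, cut = 3)
        stats::approxfun(d$x, pmax(d$y, 1e-12), rule = 2)
      })
    }
  })
  list(likelihood = likelihood, log_prior = log(prior), per_class = per_class)
}

predict_nbc <- function(fit, xn) {
  ll <- vapply(1:2, function(ci) {
    pc <- fit$per_class[[ci]]
    if (fit$likelihood == "gaussian") {
      rowSums(vapply(seq_along(pc$mean), function(j)
        stats::dnorm(xn[, j], pc$mean[j], pc$sd[j], log = TRUE),
        numeric(nrow(xn)))) + fit$log_prior[ci]
    } else {
      rowSums(vapply(seq_along(pc), function(j)
        log(pc[[j]](xn[, j])), numeric(nrow(xn)))) + fit$log_prior[ci]
    }
  }, numeric(nrow(xn)))
  as.integer(ll[, 2] > ll[, 1])
}

predict_knn <- function(fit, xn) {
  tr <- fit$x; k <- min(fit$k, nrow(tr))
  D <- if (fit$metric == "euclidean") {
    sqrt(pmax(outer(rowSums(xn^2), rowSums(tr^2), "+") -
                2 * tcrossprod(xn, tr), 0))
  } else {
    D <- matrix(0, nrow(xn), nrow(tr))
    for (j in seq_len(ncol(tr))) D <- D + abs(outer(xn[, j], tr[, j], "-"))
    D
  }
  apply(D, 1, function(d) {
    nb <- fit$y[order(d)[seq_len(k)]]
    v1 <- sum(nb == 1L) * fit$class_w[2]
    v0 <- sum(nb == 0L) * fit$class_w[1]
    as.integer(v1 > v0)  # tie goes to unripe
  })
}

#' Predict ripeness labels
#'
#' @param object A `ripeness_model`.
#' @param newdata Feature table with the model's feature columns.
#' @param ... Unused.
#' @return Integer vector of labels (0 unripe, 1 ripe).
#' @method predict ripeness_model
#' @export
predict.ripeness_model <- function(object, newdata, ...) {
  xn <- apply_normalization(object$norm, newdata)
  switch(object$spec$family,
         lr = as.integer(as.character(
           stats::predict(object$fit, newx = xn, type = "class")[, 1])),
         dt = {
           d <- as.data.frame(xn, check.names = FALSE)
           as.integer(as.character(
             stats::predict(object$fit, newdata = d, type = "class")))
         },
         nbc = predict_nbc(object$fit, xn),
         knn = predict_knn(object$fit, xn),
         svm = as.integer(as.character(stats::predict(object$fit, xn))))
}

#' Score a fitted model on a labelled feature table
#'
#' @param model A `ripeness_model`.
#' @param table Feature table with `label`.
#' @return A [score_triple()].
#' @export
evaluate_model <- function(model, table) {
  if (nrow(table) == 0) stop("empty evaluation table", call. = FALSE)
  score_triple(table$label, predict(model, table))
}

#' @method print ripeness_model
#' @export
print.ripeness_model <- function(x, ...) {
  p <- paste(names(x$spec$params),
             vapply(x$spec$params, function(v) paste(format(v), collapse = "/"),
                    character(1)),
             sep = "=", collapse = ", ")
  cat("<ripeness_model> family=", x$spec$family, " (", p, "), ",
      length(x$spec$features), " features, n_train=", x$n_train,
      if (x$spec$uniform_prior) ", uniform priors" else "", "\n", sep = "")
  invisible(x)
}

#' @method summary ripeness_model
#' @export
summary.ripeness_model <- function(object, ...) {
  print(object)
  cat("features: ", paste(object$spec$features, collapse = ", "), "\n",
      sep = "")
  invisible(object)
}
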