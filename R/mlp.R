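#' Stratified 60:20:20 split of a training table
#'
#' Partitions the rows into reduced-train (60%), validation (20%) and
#' internal-test (20%) parts, stratified by class. Each 20% part gets
#' `round(0.2 n)` rows (remainder to reduced-train), so `n = 684` splits
#' 410/137/137.
#'
#' @param train Feature table with `label` (>= 5 rows, both classes).
#' @param seed Integer seed; the partition is fixed by it.
#' @return List of class `split_indices` with integer index vectors
#'   `train`, `validation`, `internal_test`.
#' @export
split_60_20_20 <- function(train, seed = 1) {
  y <- as.integer(train$label)
  n <- length(y)
  if (n < 5 || length(unique(y)) < 2)
    stop("invalid split: need >= 5 rows with both classes", call. = FALSE)
  n_part <- floor(0.2 * n + 0.5)  # round half up
  val <- integer(0); itest <- integer(0)
  withr::with_seed(as.integer(seed), {
    # per-class allocation proportional to class size, largest classes fixed up
    idx0 <- sample(which(y == 0L)); idx1 <- sample(which(y == 1L))
    k1 <- round(n_part * length(idx1) / n)
    k0 <- n_part - k1
    if (2 * k0 > length(idx0) || 2 * k1 > length(idx1))
      stop("invalid split: a class would vanish from the reduced-train part",
           call. = FALSE)
    val <- c(idx0[seq_len(k0)], idx1[seq_len(k1)])
    itest <- c(idx0[k0 + seq_len(k0)], idx1[k1 + seq_len(k1)])
  })
  tr <- setdiff(seq_len(n), c(val, itest))
  parts <- list(train = sort(tr), validation = sort(val),
                internal_test = sort(itest))
  if (length(parts$validation) == 0 || length(parts$internal_test) == 0 ||
      length(unique(y[parts$train])) < 2)
    stop("invalid split: empty part or single-class reduced-train",
         call. = FALSE)
  structure(parts, class = "split_indices")
}

#' Registry of MLP training functions
#'
#' Eight classical optimiser configurations: plain gradient descent (`gd`),
#' gradient descent with momentum (`gdm`), adaptive-learning-rate descent
#' (`gda`), momentum plus adaptive rate (`gdx`), Fletcher--Reeves (`cg_fr`)
#' and Polak--Ribiere (`cg_pr`) conjugate gradients, quasi-Newton BFGS
#' (`bfgs`) and a Levenberg--Marquardt-type damped Gauss--Newton on the
#' network loss (`lm`). The conjugate-gradient and BFGS entries delegate to
#' [stats::optim()].
#'
#' @return Character vector of the 8 function ids.
#' @export
mlp_registry <- function() {
  c("gd", "gdm", "gda", "gdx", "cg_fr", "cg_pr", "bfgs", "lm")
}

#' MLP architecture descriptor
#'
#' @param nodes Integer vector of hidden-layer sizes (length 1 or 2,
#'   `n1 >= n2 >= 1` for two layers); total at most `max_total`.
#' @param fun Training-function id from [mlp_registry()].
#' @param seed Integer seed for weight initialisation and training.
#' @param max_total Cap on total hidden nodes (default 20).
#' @return List of class `mlp_architecture`.
#' @export
mlp_architecture <- function(nodes, fun = "bfgs", seed = 1, max_total = 20) {
  nodes <- as.integer(nodes)
  if (!length(nodes) %in% 1:2 || any(nodes < 1))
    stop("1 or 2 hidden layers with >= 1 node each", call. = FALSE)
  if (sum(nodes) > max_total)
    stop("total hidden nodes exceeds ", max_total, call. = FALSE)
  if (length(nodes) == 2 && nodes[1] < nodes[2])
    stop("two-layer architectures require n1 >= n2", call. = FALSE)
  if (!fun %in% mlp_registry())
    stop("unknown training function '", fun, "'", call. = FALSE)
  structure(list(nodes = nodes, fun = fun, seed = as.integer(seed)),
            class = "mlp_architecture")
}

# ---- network internals (tanh hidden layers, softmax output) ----------------

mlp_dims <- function(p, nodes) {
  h1 <- nodes[1]; h2 <- if (length(nodes) == 2) nodes[2] else 0L
  hl <- if (h2 > 0) h2 else h1
  c(p = p, h1 = h1, h2 = h2, hl = hl,
    n_par = p * h1 + h1 + (if (h2) h1 * h2 + h2 else 0L) + hl * 2 + 2)
}

mlp_unpack <- function(theta, d) {
  i <- 0L
  take <- function(k) {
    v <- theta[i + seq_len(k)]; i <<- i + k; v
  }
  W1 <- matrix(take(d["p"] * d["h1"]), d["p"], d["h1"])
  b1 <- take(d["h1"])
  W2 <- NULL; b2 <- NULL
  if (d["h2"] > 0) {
    W2 <- matrix(take(d["h1"] * d["h2"]), d["h1"], d["h2"])
    b2 <- take(d["h2"])
  }
  Wo <- matrix(take(d["hl"] * 2), d["hl"], 2)
  bo <- take(2)
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, Wo = Wo, bo = bo)
}

mlp_forward <- function(theta, d, X) {
  w <- mlp_unpack(theta, d)
  A1 <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  A2 <- if (d["h2"] > 0) tanh(sweep(A1 %*% w$W2, 2, w$b2, "+")) else NULL
  AL <- if (is.null(A2)) A1 else A2
  Z <- sweep(AL %*% w$Wo, 2, w$bo, "+")
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  P <- E / rowSums(E)
  list(w = w, A1 = A1, A2 = A2, AL = AL, P = P)
}

# Weighted cross-entropy loss; cw = per-sample weights (mean 1).
mlp_loss <- function(theta, d, X, y, cw) {
  P <- mlp_forward(theta, d, X)$P
  p_true <- P[cbind(seq_along(y), y + 1L)]
  -mean(cw * log(pmax(p_true, 1e-12)))
}

mlp_grad <- function(theta, d, X, y, cw) {
  f <- mlp_forward(theta, d, X)
  n <- nrow(X)
  Tm <- matrix(0, n, 2); Tm[cbind(seq_len(n), y + 1L)] <- 1
  dZ <- (f$P - Tm) * (cw / n)
  gWo <- crossprod(f$AL, dZ)
  gbo <- colSums(dZ)
  dAL <- tcrossprod(dZ, f$w$Wo)
  if (d["h2"] > 0) {
    dP2 <- dAL * (1 - f$A2^2)
    gW2 <- crossprod(f$A1, dP2)
    gb2 <- colSums(dP2)
    dA1 <- tcrossprod(dP2, f$w$W2)
  } else {
    gW2 <- NULL; gb2 <- NULL
    dA1 <- dAL
  }
  dP1 <- dA1 * (1 - f$A1^2)
  gW1 <- crossprod(X, dP1)
  gb1 <- colSums(dP1)
  c(as.vector(gW1), gb1,
    if (d["h2"] > 0) c(as.vector(gW2), gb2),
    as.vector(gWo), gbo)
}

# Jacobian (n x n_par) of the logit difference z1 - z2 w.r.t. theta.
# For 2-class softmax the Fisher/Gauss-Newton matrix reduces to
# t(J) %*% (J * w * p1 * p2), so this one matrix drives the LM step.
mlp_diff_jacobian <- function(theta, d, X) {
  f <- mlp_forward(theta, d, X)
  n <- nrow(X)
  dwo <- f$w$Wo[, 1] - f$w$Wo[, 2]            # hl
  DL <- matrix(dwo, n, d["hl"], byrow = TRUE)  # d(z1-z2)/d AL
  if (d["h2"] > 0) {
    D2 <- DL * (1 - f$A2^2)                   # w.r.t. layer-2 preact
    D1 <- tcrossprod(D2, f$w$W2) * (1 - f$A1^2)
  } else {
    D1 <- DL * (1 - f$A1^2)
  }
  kr <- function(A, B) {
    # row-wise Khatri-Rao matching column-major W packing: col (a-1)*p + c
    A[, rep(seq_len(ncol(A)), times = ncol(B)), drop = FALSE] *
      B[, rep(seq_len(ncol(B)), each = ncol(A)), drop = FALSE]
  }
  J <- cbind(kr(X, D1), D1)
  if (d["h2"] > 0) J <- cbind(J, kr(f$A1, D2), D2)
  cbind(J, f$AL, -f$AL,
        matrix(1, n, 1), matrix(-1, n, 1))[, , drop = FALSE]
}

# One damped Gauss-Newton (LM-type) update; returns list(theta, loss, lambda).
mlp_lm_step <- function(theta, d, X, y, cw, lambda) {
  f <- mlp_forward(theta, d, X)
  n <- nrow(X)
  J <- mlp_diff_jacobian(theta, d, X)
  r <- (f$P[, 1] - as.numeric(y == 0L)) * cw / n     # d loss / d (z1 - z2)
  g <- crossprod(J, r)[, 1]
  s <- f$P[, 1] * f$P[, 2] * cw / n
  Fm <- crossprod(J, J * s)
  loss0 <- mlp_loss(theta, d, X, y, cw)
  dg <- pmax(diag(Fm), 1e-8)
  for (tries in 1:8) {
    step <- tryCatch(solve(Fm + lambda * diag(dg), -g),
                     error = function(e) NULL)
    if (!is.null(step)) {
      cand <- theta + as.vector(step)
      loss1 <- mlp_loss(cand, d, X, y, cw)
      if (is.finite(loss1) && loss1 < loss0)
        return(list(theta = cand, loss = loss1, lambda = max(lambda / 3, 1e-8)))
    }
    lambda <- lambda * 5
  }
  list(theta = theta, loss = loss0, lambda = lambda)
}

#' Train a multi-layer perceptron with early stopping
#'
#' Input width = number of features, two softmax output nodes, tanh hidden
#' activations, class-weighted cross-entropy (uniform priors). Training runs
#' on the reduced-train part of the split; after every epoch the validation
#' F1 is recorded and training stops when it has not improved for `patience`
#' epochs. The weights attaining the best validation F1 are restored.
#'
#' @param arch An [mlp_architecture()].
#' @param split A [split_60_20_20()] result for `table`.
#' @param table Feature table with `label` and the feature columns.
#' @param features Feature columns (default all 18).
#' @param max_epochs,patience Early-stopping settings.
#' @param lr Base learning rate for the gradient-descent family.
#' @param steps_per_epoch Gradient/optimiser steps between validation checks.
#' @return Object of class `mlp_model`: weights, normalisation statistics,
#'   training history (`epoch`, `loss`, `val_f1`), `best_val_f1`.
#' @export
train_mlp <- function(arch, split, table, features = feature_names(),
                      max_epochs = 500, patience = 10, lr = 0.1,
                      steps_per_epoch = 10) {
  stopifnot(inherits(arch, "mlp_architecture"),
            inherits(split, "split_indices"))
  tr <- table[split$train, , drop = FALSE]
  va <- table[split$validation, , drop = FALSE]
  norm <- fit_normalization(tr[, features, drop = FALSE])
  X <- apply_normalization(norm, tr)
  y <- as.integer(tr$label)
  Xv <- apply_normalization(norm, va)
  yv <- as.integer(va$label)
  cw <- prior_weights(y)
  cw <- cw / mean(cw)
  d <- mlp_dims(ncol(X), arch$nodes)

  val_f1 <- function(theta) {
    pred <- as.integer(mlp_forward(theta, d, Xv)$P[, 2] > 0.5)
    fbeta_score(confusion_counts(yv, pred), 1)
  }

  theta <- withr::with_seed(arch$seed,
                            stats::rnorm(d["n_par"], 0, 0.5 / sqrt(d["p"])))
  state <- list(v = numeric(d["n_par"]), lr = lr, lambda = 1e-2,
                loss = mlp_loss(theta, d, X, y, cw))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_f1 = numeric(0))
  best <- list(theta = theta, f1 = val_f1(theta), epoch = 0L)
  stall <- 0L

  for (epoch in seq_len(max_epochs)) {
    if (arch$fun %in% c("gd", "gdm", "gda", "gdx")) {
      mom <- arch$fun %in% c("gdm", "gdx")
      adapt <- arch$fun %in% c("gda", "gdx")
      for (s in seq_len(steps_per_epoch)) {
        g <- mlp_grad(theta, d, X, y, cw)
        v <- if (mom) 0.9 * state$v - state$lr * g else -state$lr * g
        cand <- theta + v
        if (adapt) {
          l1 <- mlp_loss(cand, d, X, y, cw)
          if (is.finite(l1) && l1 <= state$loss * 1.04) {
            theta <- cand; state$v <- v; state$loss <- l1
            state$lr <- state$lr * 1.05
          } else {                       # reject step, cool down
            state$lr <- state$lr * 0.7
            state$v <- numeric(d["n_par"])
          }
        } else {
          theta <- cand; state$v <- v
        }
      }
      if (!adapt) state$loss <- mlp_loss(theta, d, X, y, cw)
    } else if (arch$fun %in% c("cg_fr", "cg_pr", "bfgs")) {
      ctl <- list(maxit = steps_per_epoch)
      if (arch$fun != "bfgs") ctl$type <- if (arch$fun == "cg_fr") 1 else 2
      opt <- stats::optim(theta, fn = mlp_loss, gr = mlp_grad,
                          d = d, X = X, y = y, cw = cw,
                          method = if (arch$fun == "bfgs") "BFGS" else "CG",
                          control = ctl)
      theta <- opt$par
      state$loss <- opt$value
    } else {                             # lm
      st <- mlp_lm_step(theta, d, X, y, cw, state$lambda)
      theta <- st$theta; state$loss <- st$loss; state$lambda <- st$lambda
    }
    if (!is.finite(state$loss)) {
      err <- simpleError("mlp training failure: non-finite loss")
      err$history <- history
      stop(err)
    }
    f1 <- val_f1(theta)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = state$loss,
                                val_f1 = f1))
    if (f1 > best$f1) {
      best <- list(theta = theta, f1 = f1, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  structure(list(arch = arch, dims = d, theta = best$theta, norm = norm,
                 features = features, history = history,
                 best_val_f1 = best$f1, best_epoch = best$epoch),
            class = "mlp_model")
}

#' @method predict mlp_model
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- apply_normalization(object$norm, newdata)
  as.integer(mlp_forward(object$theta, object$dims, X)$P[, 2] > 0.5)
}

#' @method print mlp_model
#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> ", length(x$arch$nodes), " hidden layer(s) [",
      paste(x$arch$nodes, collapse = ","), "], fun=", x$arch$fun,
      ", best val F1=", format(x$best_val_f1, digits = 3),
      " @ epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Enumerate admissible architectures
#'
#' 1-layer sizes `1..max_nodes` and 2-layer pairs with
#' `n1 >= n2 >= 1`, `n1 + n2 <= max_nodes`, ordered by total nodes then
#' layer count (the tie-break order of the search).
#'
#' @param max_nodes Cap on total hidden nodes.
#' @param layers Which layer counts to include (subset of `c(1, 2)`).
#' @return List of integer node vectors.
#' @export
enumerate_architectures <- function(max_nodes = 20, layers = c(1, 2)) {
  stopifnot(max_nodes >= 1, all(layers %in% 1:2))
  cand <- list()
  if (1 %in% layers)
    cand <- c(cand, lapply(seq_len(max_nodes), function(n) n))
  if (2 %in% layers && max_nodes >= 2) {
    for (n1 in 1:(max_nodes - 1))
      for (n2 in 1:min(n1, max_nodes - n1))
        cand <- c(cand, list(c(n1, n2)))
  }
  tot <- vapply(cand, sum, numeric(1))
  nl <- vapply(cand, length, numeric(1))
  cand[order(tot, nl)]
}

#' Node-count search for one training function
#'
#' Trains every admissible architecture for the given training function on
#' the split and selects the one with the best internal-test F-beta. Ties
#' break toward fewer total nodes, then fewer layers.
#'
#' @param fun Training-function id.
#' @param table Feature table.
#' @param split A [split_60_20_20()] result.
#' @param max_nodes Cap on total hidden nodes (default 20).
#' @param layers Layer counts to consider.
#' @param beta F-score weighting for selection.
#' @param seed Seed used for every candidate's initialisation.
#' @param ... Passed to [train_mlp()].
#' @return The winning [mlp_architecture()], with attributes `score` (its
#'   internal-test F-beta) and `log` (per-candidate results).
#' @export
search_architecture <- function(fun, table, split, max_nodes = 20,
                                layers = c(1, 2), beta = 1, seed = 1, ...) {
  cand <- enumerate_architectures(max_nodes, layers)
  it <- table[split$internal_test, , drop = FALSE]
  log <- data.frame()
  best <- NULL; best_score <- -Inf
  for (nodes in cand) {
    arch <- mlp_architecture(nodes, fun, seed = seed, max_total = max_nodes)
    m <- train_mlp(arch, split, table, ...)
    sc <- fbeta_score(confusion_counts(it$label, predict(m, it)), beta)
    log <- rbind(log, data.frame(
      fun = fun, layers = length(nodes), n1 = nodes[1],
      n2 = if (length(nodes) == 2) nodes[2] else NA_integer_,
      val_f1 = m$best_val_f1, internal_test = sc, epochs = m$best_epoch))
    if (sc > best_score) {               # strict: earlier (simpler) wins ties
      best <- arch; best_score <- sc
    }
  }
  attr(best, "score") <- best_score
  attr(best, "log") <- log
  best
}

#' Two-stage training-function selection
#'
#' Stage 1: for every registry function, find its best node count on a first
#' 60:20:20 split. Stage 2: retrain each winner on a second seeded split and
#' keep the function with the best internal-test F-beta. The returned model
#' is the frozen stage-2 winner, ready for external testing.
#'
#' @param table Feature table.
#' @param registry Training-function ids (default all 8).
#' @param max_nodes,layers,beta As in [search_architecture()].
#' @param seed Base seed; stage-1 and stage-2 splits use `seed` and
#'   `seed + 1`.
#' @param ... Passed to [train_mlp()].
#' @return List of class `mlp_selection`: `model` (an `mlp_model`), `fun`,
#'   `arch`, `stage1` and `stage2` logs.
#' @export
select_training_function <- function(table, registry = mlp_registry(),
                                     max_nodes = 20, layers = c(1, 2),
                                     beta = 1, seed = 1, ...) {
  stopifnot(length(registry) >= 1, all(registry %in% mlp_registry()))
  split1 <- split_60_20_20(table, seed)
  split2 <- split_60_20_20(table, seed + 1L)
  it2 <- table[split2$internal_test, , drop = FALSE]
  stage1 <- list(); stage2 <- data.frame()
  best <- NULL; best_score <- -Inf
  for (fun in registry) {
    a <- search_architecture(fun, table, split1, max_nodes, layers, beta,
                             seed = seed, ...)
    stage1[[fun]] <- attr(a, "log")
    m2 <- train_mlp(mlp_architecture(a$nodes, fun, seed = seed,
                                     max_total = max_nodes),
                    split2, table, ...)
    sc <- fbeta_score(confusion_counts(it2$label, predict(m2, it2)), beta)
    stage2 <- rbind(stage2, data.frame(
      fun = fun, layers = length(a$nodes), n1 = a$nodes[1],
      n2 = if (length(a$nodes) == 2) a$nodes[2] else NA_integer_,
      internal_test = sc))
    if (sc > best_score) {
      best <- list(model = m2, fun = fun, arch = a)
      best_score <- sc
    }
  }
  structure(c(best, list(stage1 = stage1, stage2 = stage2,
                         score = best_score)),
            class = "mlp_selection")
}
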