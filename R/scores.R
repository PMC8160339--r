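#' Column-wise z-score normalisation statistics
#'
#' Learns per-feature center (mean) and scale (sample sd) from training rows;
#' test rows must always be transformed with the training statistics.
#'
#' @param x Numeric matrix or data.frame of feature columns (training rows).
#' @return List of class `normalization_stats` with `center` and `scale`.
#' @export
fit_normalization <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty training table", call. = FALSE)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  bad <- !is.finite(scale) | scale == 0
  if (any(bad))
    stop("degenerate feature (constant column): ",
         paste(colnames(x)[bad], collapse = ", "), call. = FALSE)
  structure(list(center = center, scale = scale),
            class = "normalization_stats")
}

#' Apply learned z-score normalisation
#'
#' @param stats A [fit_normalization()] result.
#' @param x Matrix/data.frame with (a superset of) the learned columns.
#' @return Numeric matrix of the learned columns, centered and scaled.
#' @export
apply_normalization <- function(stats, x) {
  stopifnot(inherits(stats, "normalization_stats"))
  if (is.data.frame(x)) x <- x[, names(stats$center), drop = FALSE]
  x <- as.matrix(x)[, names(stats$center), drop = FALSE]
  sweep(sweep(x, 2, stats$center, "-"), 2, stats$scale, "/")
}

#' Confusion counts for binary ripeness predictions
#'
#' @param truth,pred Integer/logical vectors; positive class is ripe (1).
#' @return List of class `confusion_counts`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth); pred <- as.integer(pred)
  structure(list(tp = sum(truth == 1L & pred == 1L),
                 fp = sum(truth == 0L & pred == 1L),
                 fn = sum(truth == 1L & pred == 0L),
                 tn = sum(truth == 0L & pred == 0L)),
            class = "confusion_counts")
}

#' F-beta score from confusion counts
#'
#' `F_beta = (beta^2 + 1) P R / (beta^2 P + R)` with precision
#' `P = tp / (tp + fp)` and recall `R = tp / (tp + fn)`. `beta = 1` balances
#' the two, `beta < 1` favours precision, `beta > 1` favours recall. Edge
#' cases: no true positives with any error present scores 0; a perfect
#' prediction (no fp, no fn, some tp) scores 1; an all-empty confusion
#' (tp = fp = fn = 0) is defined as 0 with a warning.
#'
#' @param c A [confusion_counts()] object (or list with tp/fp/fn/tn).
#' @param beta Positive weighting parameter.
#' @return Scalar in `[0, 1]`.
#' @examples
#' fbeta_score(confusion_counts(c(1, 1, 0), c(1, 0, 0)), beta = 1)
#' @export
fbeta_score <- function(c, beta = 1) {
  if (!is.finite(beta) || beta <= 0)
    stop("beta must be a positive real", call. = FALSE)
  tp <- c$tp; fp <- c$fp; fn <- c$fn
  if (tp + fp + c$tn + fn < 1) stop("empty confusion", call. = FALSE)
  if (tp == 0) {
    if (fp == 0 && fn == 0) {
      warning("no positives anywhere (tp = fp = fn = 0): F defined as 0",
              call. = FALSE)
      return(0)
    }
    return(0)
  }
  if (fp == 0 && fn == 0) return(1)
  P <- tp / (tp + fp)
  R <- tp / (tp + fn)
  (beta^2 + 1) * P * R / (beta^2 * P + R)
}

#' Precision, recall and the three F scores for a prediction
#'
#' @param truth,pred Binary label vectors (1 = ripe).
#' @return List of class `score_triple`: `precision`, `recall`, `f1`, `f05`,
#'   `f2`, `confusion`.
#' @export
score_triple <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  P <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_
  R <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  structure(list(precision = P, recall = R,
                 f1 = fbeta_score(cc, 1), f05 = fbeta_score(cc, 0.5),
                 f2 = fbeta_score(cc, 2), confusion = cc),
            class = "score_triple")
}
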