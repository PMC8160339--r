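#' Nested likelihood-ratio comparison for one feature
#'
#' Fits three nested linear models of the colour coordinate a* by maximum
#' likelihood -- feature only (`a* ~ X`), additive (`a* ~ X + Z`) and
#' interaction (`a* ~ X * Z`) with `Z` the fruit size -- and compares each
#' nested pair with a likelihood-ratio test (statistic `2 * dlogLik`,
#' chi-square with 1 df). A small `p_main` says adding size improves the
#' description of colour; a small `p_interaction` says the size effect
#' depends on the feature level.
#'
#' Size is treated as a fixed continuous covariate: a per-observation
#' continuous "random effect" is unidentifiable in this design, and the
#' model formulas above are covariate-style.
#'
#' @param feature Numeric vector of one bioimpedance feature.
#' @param size Fruit sizes (mm), same length.
#' @param a_star Colour coordinate a*, same length.
#' @param name Feature name used in error messages and output.
#' @return List of class `lme_comparison`: `feature`, `p_main`,
#'   `p_interaction`, `loglik_f`, `loglik_add`, `loglik_int`, `lrt_main`,
#'   `lrt_interaction`.
#' @export
fit_and_compare <- function(feature, size, a_star, name = "feature") {
  n <- length(a_star)
  if (length(feature) != n || length(size) != n || n < 10)
    stop("need equal-length vectors with at least 10 observations",
         call. = FALSE)
  if (!all(is.finite(feature)) || !all(is.finite(size)) ||
      !all(is.finite(a_star)))
    stop("non-finite values in the design", call. = FALSE)
  if (stats::sd(feature) == 0)
    stop("degenerate design: constant column '", name, "'", call. = FALSE)
  if (stats::sd(size) == 0)
    stop("degenerate design: constant column 'size_mm'", call. = FALSE)
  d <- data.frame(y = a_star, x = feature, z = size)
  m_f <- stats::lm(y ~ x, data = d)
  m_a <- stats::lm(y ~ x + z, data = d)
  m_i <- stats::lm(y ~ x * z, data = d)
  ll <- vapply(list(m_f, m_a, m_i), function(m) as.numeric(stats::logLik(m)),
               numeric(1))
  lrt_main <- 2 * (ll[2] - ll[1])
  lrt_int <- 2 * (ll[3] - ll[2])
  structure(list(feature = name,
                 p_main = stats::pchisq(lrt_main, df = 1, lower.tail = FALSE),
                 p_interaction = stats::pchisq(lrt_int, df = 1,
                                               lower.tail = FALSE),
                 loglik_f = ll[1], loglik_add = ll[2], loglik_int = ll[3],
                 lrt_main = lrt_main, lrt_interaction = lrt_int),
            class = "lme_comparison")
}

#' Likelihood-ratio screen of the size covariate over all 17 features
#'
#' Runs [fit_and_compare()] for each bioimpedance-derived feature in the
#' canonical column order. Size qualifies as a "correction" feature when the
#' additive model beats the feature-only model (`p_main <= alpha`) for a
#' configured majority of features (default: all 17).
#'
#' @param table Feature table from [assemble_features()] (needs the 17
#'   features plus `size_mm` and `a_star`).
#' @param alpha Significance level (inclusive), default 0.05.
#' @param require_frac Fraction of features that must have
#'   `p_main <= alpha` for `include_size` to be `TRUE`; default 1.
#' @return A `data.frame` of class `size_screen` with one row per feature
#'   (`feature`, `p_main`, `p_interaction`, `loglik_f`, `loglik_add`,
#'   `loglik_int`) and attribute `include_size`.
#' @export
screen_all <- function(table, alpha = 0.05, require_frac = 1) {
  feats <- feature_names(with_size = FALSE)
  missing <- setdiff(c(feats, "size_mm", "a_star"), names(table))
  if (length(missing))
    stop("feature table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(feats, function(f) {
    cmp <- tryCatch(fit_and_compare(table[[f]], table$size_mm, table$a_star,
                                    name = f),
                    error = function(e)
                      stop("size screen failed for '", f, "': ",
                           conditionMessage(e), call. = FALSE))
    data.frame(feature = f, p_main = cmp$p_main,
               p_interaction = cmp$p_interaction, loglik_f = cmp$loglik_f,
               loglik_add = cmp$loglik_add, loglik_int = cmp$loglik_int,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "include_size") <- mean(out$p_main <= alpha) >= require_frac
  class(out) <- c("size_screen", "data.frame")
  out
}
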