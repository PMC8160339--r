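#' Median correlation curves of a spectral parameter with colour and size
#'
#' For one derived parameter (magnitude, phase or loss tangent), computes at
#' every grid point the median, over bootstrap resamples of the fruit, of the
#' correlation between the parameter value at that frequency and (a) the
#' colour coordinate a* and (b) the fruit size. Rank (Spearman) correlation
#' is the default because impedance--colour associations are monotone rather
#' than linear; `n_boot = 1` reduces to a plain correlation of the full set.
#'
#' @param ds A `fruit_dataset` (training fruit).
#' @param parameter One of `"magnitude"`, `"phase"`, `"tan_delta"`.
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Integer seed for the resampling stream.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List of class `correlation_curves`: `parameter`, `freq_hz`,
#'   `r_color`, `r_size` (each per grid point, in `[-1, 1]`).
#' @export
correlation_curves <- function(ds, parameter = c("magnitude", "phase",
                                                 "tan_delta"),
                               n_boot = 100, seed = 1,
                               method = c("spearman", "pearson")) {
  parameter <- match.arg(parameter)
  method <- match.arg(method)
  stopifnot(inherits(ds, "fruit_dataset"), n_boot >= 1)
  n <- length(ds$fruit_id)
  if (n < 3) stop("need at least 3 fruit", call. = FALSE)
  X <- parameter_matrix(ds, parameter)
  targ <- cbind(color = ds$a_star, size = ds$size)
  boots <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- if (n_boot == 1L) seq_len(n) else sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(X[idx, , drop = FALSE],
                                  targ[idx, , drop = FALSE], method = method))
    })
  })
  rc <- apply(vapply(boots, function(m) m[, "color"], numeric(ncol(X))), 1,
              stats::median)
  rs <- apply(vapply(boots, function(m) m[, "size"], numeric(ncol(X))), 1,
              stats::median)
  zv <- !is.finite(rc) | !is.finite(rs)
  if (any(zv)) {
    warning("zero-variance parameter at ", sum(zv),
            " grid point(s): correlation set to 0", call. = FALSE)
    rc[!is.finite(rc)] <- 0
    rs[!is.finite(rs)] <- 0
  }
  structure(list(parameter = parameter, freq_hz = ds$grid,
                 r_color = rc, r_size = rs),
            class = "correlation_curves")
}

# n x n_freq matrix of one derived parameter for all fruit.
parameter_matrix <- function(ds, parameter) {
  switch(parameter,
         magnitude = Mod(ds$z),
         phase = Arg(ds$z) * 180 / pi,
         tan_delta = {
           im <- Im(ds$z)
           td <- Re(ds$z) / abs(im)
           td[im == 0] <- 1e6
           td
         })
}

#' Select frequency points where colour correlation dominates size
#'
#' Operationalises the by-eye choice of "interesting correlation behaviour":
#' with `D(f) = |r_color(f)| - |r_size(f)|`, candidates are the zero
#' crossings of `D` (ranked by the local slope `|dD/dlog f|`) and its
#' interior local maxima (ranked by `|D|`). Candidates are picked greedily in
#' descending rank, enforcing a minimum log-spacing between picks (neighbour
#' frequencies are strongly autocorrelated); ties break toward the lower
#' frequency. If fewer than `k` candidates survive, the remainder is filled
#' with evenly log-spaced grid points.
#'
#' @param curves A [correlation_curves()] result.
#' @param k Number of points to select (default 5).
#' @param min_sep Minimum separation between picks, in decades (default 0.3).
#' @return Strictly increasing numeric vector of `k` grid frequencies.
#' @export
select_frequency_points <- function(curves, k = 5, min_sep = 0.3) {
  stopifnot(inherits(curves, "correlation_curves"), k >= 1)
  f <- curves$freq_hz
  n <- length(f)
  if (n < k) stop("grid shorter than k", call. = FALSE)
  lf <- log10(f)
  D <- abs(curves$r_color) - abs(curves$r_size)
  slope <- c(0, diff(D) / diff(lf))

  cand_idx <- integer(0); cand_score <- numeric(0)
  # zero crossings: sign change between neighbours; keep the grid point of
  # the pair with smaller |D|, scored by the crossing slope magnitude
  sg <- sign(D)
  for (i in seq_len(n - 1)) {
    if (sg[i] != 0 && sg[i + 1] != 0 && sg[i] != sg[i + 1]) {
      j <- if (abs(D[i]) <= abs(D[i + 1])) i else i + 1L
      cand_idx <- c(cand_idx, j)
      cand_score <- c(cand_score, abs(slope[i + 1]))
    }
  }
  # interior local maxima of D
  for (i in 2:(n - 1)) {
    if (D[i] > D[i - 1] && D[i] >= D[i + 1]) {
      cand_idx <- c(cand_idx, i)
      cand_score <- c(cand_score, abs(D[i]))
    }
  }
  keep <- !duplicated(cand_idx)
  cand_idx <- cand_idx[keep]; cand_score <- cand_score[keep]
  ord <- order(-cand_score, f[cand_idx])
  cand_idx <- cand_idx[ord]

  picked <- integer(0)
  for (j in cand_idx) {
    if (length(picked) == k) break
    if (all(abs(lf[j] - lf[picked]) >= min_sep)) picked <- c(picked, j)
  }
  n_candidates <- length(picked)
  if (length(picked) < k) {
    fill <- unique(round(seq(1, n, length.out = k)))
    fill <- setdiff(fill, picked)
    for (j in fill) {
      if (length(picked) == k) break
      picked <- c(picked, j)
    }
    # last resort: any remaining grid point, lowest frequency first
    for (j in setdiff(seq_len(n), picked)) {
      if (length(picked) == k) break
      picked <- c(picked, j)
    }
  }
  out <- sort(f[picked])
  attr(out, "n_candidates") <- n_candidates
  out
}

#' Select 5 frequency points for each spectral parameter
#'
#' Runs [correlation_curves()] and [select_frequency_points()] for magnitude,
#' phase and loss tangent on the training fruit.
#'
#' @inheritParams correlation_curves
#' @inheritParams select_frequency_points
#' @return List with elements `magnitude`, `phase`, `tan_delta` (5
#'   frequencies each) and `curves` (the three correlation curves).
#' @export
screen_frequencies <- function(ds, n_boot = 100, seed = 1, k = 5,
                               min_sep = 0.3,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  pars <- c("magnitude", "phase", "tan_delta")
  curves <- lapply(pars, function(p)
    correlation_curves(ds, p, n_boot = n_boot, seed = seed, method = method))
  names(curves) <- pars
  sel <- lapply(curves, function(cv)
    as.numeric(select_frequency_points(cv, k = k, min_sep = min_sep)))
  c(sel, list(curves = curves))
}
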