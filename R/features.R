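#' Derived spectral curves: magnitude, phase, loss tangent
#'
#' Turns a complex impedance spectrum into the three per-frequency curves the
#' pipeline works with: magnitude `|Z|` (ohms), signed phase angle `phi`
#' (degrees, in `(-90, 0]` for capacitive tissue) and the loss tangent
#' `tan(delta)` with `delta = 90 - |phi|` degrees, equivalently
#' `Re(z) / |Im(z)|`.
#'
#' @param z Complex impedance vector (one value per grid point).
#' @param tand_ceiling Cap for `tan(delta)` where `Im(z) == 0`; such points
#'   trigger a warning.
#' @return List of class `derived_curves` with numeric vectors `magnitude`,
#'   `phase`, `tan_delta`.
#' @examples
#' derive_curves(complex(real = 1, imaginary = -1))
#' @export
derive_curves <- function(z, tand_ceiling = 1e6) {
  stopifnot(is.complex(z), length(z) >= 1)
  magnitude <- Mod(z)
  phase <- Arg(z) * 180 / pi
  im0 <- Im(z) == 0
  tan_delta <- rep(tand_ceiling, length(z))
  tan_delta[!im0] <- Re(z)[!im0] / abs(Im(z)[!im0])
  tan_delta <- pmin(tan_delta, tand_ceiling)
  if (any(im0))
    warning("purely real impedance at ", sum(im0),
            " point(s): tan_delta capped at ", tand_ceiling, call. = FALSE)
  structure(list(magnitude = magnitude, phase = phase, tan_delta = tan_delta),
            class = "derived_curves")
}

#' Relative magnitude drop index Py
#'
#' `Py = 1 - |Z|(fmax) / |Z|(fmin)`: the relative fall of the impedance
#' magnitude from the lowest to the highest measured frequency. For a
#' single-dispersion spectrum with both plateaus inside the band this
#' approaches `1 - Rinf / R0`, tying the index to the low- and
#' high-frequency resistances without any circuit fitting. The geometry
#' factor of the measurement cancels, making Py size-invariant.
#'
#' @param curves A [derive_curves()] result.
#' @return Dimensionless scalar.
#' @export
compute_py <- function(curves) {
  stopifnot(inherits(curves, "derived_curves"))
  m <- curves$magnitude
  if (m[1] == 0) stop("invalid spectrum: |Z| at fmin is zero", call. = FALSE)
  1 - m[length(m)] / m[1]
}

#' Minimum phase of a spectrum
#'
#' The most negative phase value over the grid (a scalar feature; the
#' frequency at which it occurs is not retained). Ties resolve to the lowest
#' frequency, which does not change the returned value.
#'
#' @param curves A [derive_curves()] result.
#' @return Phase in degrees.
#' @export
compute_min_phase <- function(curves) {
  stopifnot(inherits(curves, "derived_curves"))
  curves$phase[which.min(curves$phase)]
}

#' Canonical feature names
#'
#' The 17 bioimpedance-derived features (5 magnitude + 5 phase + 5 loss
#' tangent frequencies, Py, minimum phase) plus fruit size, in the fixed
#' column order used by every downstream stage.
#'
#' @param with_size Include `size_mm` (default `TRUE`).
#' @return Character vector of 18 (or 17) names.
#' @export
feature_names <- function(with_size = TRUE) {
  nm <- c(paste0("magn_f", 1:5), paste0("phase_f", 1:5), paste0("tand_f", 1:5),
          "py", "min_phase")
  if (with_size) nm <- c(nm, "size_mm")
  nm
}

#' Assemble the per-fruit feature table
#'
#' Evaluates the three derived curves at the selected frequency points (which
#' must be exact grid members; no interpolation), adds Py, minimum phase and
#' fruit size, and returns one row per fruit in the input order.
#'
#' @param ds A `fruit_dataset`.
#' @param sel Selected frequencies: list with numeric vectors `magnitude`,
#'   `phase`, `tan_delta` (5 each), e.g. from [select_frequency_points()].
#' @return A `data.frame` with columns `fruit_id`, `label`, the 18 features
#'   in [feature_names()] order, and `a_star` (kept for the size screen).
#' @export
assemble_features <- function(ds, sel) {
  stopifnot(inherits(ds, "fruit_dataset"))
  for (par in c("magnitude", "phase", "tan_delta")) {
    if (length(sel[[par]]) != 5)
      stop("need exactly 5 selected frequencies for ", par, call. = FALSE)
  }
  idx <- lapply(sel[c("magnitude", "phase", "tan_delta")], function(f) {
    # grid membership up to printing precision (no interpolation)
    i <- vapply(f, function(fi) which.min(abs(ds$grid - fi)), integer(1))
    off <- abs(ds$grid[i] - f) / f > 1e-6
    if (any(off))
      stop("selected frequency not on the acquisition grid: ",
           paste(f[off], collapse = ", "), call. = FALSE)
    i
  })
  n <- length(ds$fruit_id)
  feat <- matrix(NA_real_, n, 17,
                 dimnames = list(NULL, feature_names(with_size = FALSE)))
  for (i in seq_len(n)) {
    cur <- derive_curves(ds$z[i, ])
    feat[i, ] <- c(cur$magnitude[idx$magnitude], cur$phase[idx$phase],
                   cur$tan_delta[idx$tan_delta], compute_py(cur),
                   compute_min_phase(cur))
  }
  out <- data.frame(fruit_id = ds$fruit_id, label = ds$label, feat,
                    size_mm = ds$size, a_star = ds$a_star,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
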