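#' Logarithmically spaced frequency grid
#'
#' Builds the acquisition grid used throughout the pipeline: `n` points with a
#' constant ratio between consecutive frequencies, spanning `[fmin, fmax]`.
#' The default mirrors a bench-top sweep of 300 points over 20 Hz--300 kHz.
#'
#' @param n Number of points (>= 2).
#' @param fmin,fmax Band edges in Hz, `0 < fmin < fmax`.
#' @return Numeric vector of length `n`, strictly increasing, `[1] == fmin`,
#'   `[n] == fmax`.
#' @examples
#' f <- make_frequency_grid(300, 20, 3e5)
#' range(f)
#' @export
make_frequency_grid <- function(n = 300, fmin = 20, fmax = 3e5) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (!is.finite(fmin) || !is.finite(fmax) || fmin <= 0 || fmax <= fmin)
    stop("need 0 < fmin < fmax", call. = FALSE)
  f <- exp(seq(log(fmin), log(fmax), length.out = as.integer(n)))
  f[1] <- fmin
  f[length(f)] <- fmax
  f
}

#' Single-dispersion Cole parameters
#'
#' Container for the four parameters of the single-dispersion Cole model of
#' tissue impedance: zero-frequency resistance `R0`, infinite-frequency
#' resistance `Rinf`, characteristic time `tau` and the constant-phase-element
#' exponent `alpha`.
#'
#' @param R0 Zero-frequency resistance in ohms; `R0 > Rinf`.
#' @param Rinf Infinite-frequency resistance in ohms; `> 0`.
#' @param tau Characteristic time in seconds; `> 0`.
#' @param alpha CPE exponent in `(0, 1]`.
#' @return An object of class `cole_params`.
#' @examples
#' cole_params(100, 20, 1e-4, 0.8)
#' @export
cole_params <- function(R0, Rinf, tau, alpha = 1) {
  stopifnot(length(R0) == 1, length(Rinf) == 1, length(tau) == 1,
            length(alpha) == 1)
  if (!is.finite(Rinf) || Rinf <= 0 || !is.finite(R0) || R0 <= Rinf)
    stop("require R0 > Rinf > 0", call. = FALSE)
  if (!is.finite(tau) || tau <= 0)
    stop("require tau > 0", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("require 0 < alpha <= 1", call. = FALSE)
  structure(list(R0 = R0, Rinf = Rinf, tau = tau, alpha = alpha),
            class = "cole_params")
}

#' Noiseless Cole impedance kernel
#'
#' Evaluates `Z(w) = Rinf + (R0 - Rinf) / (1 + (j w tau)^alpha)` at the given
#' frequencies (Hz), optionally scaled by a multiplicative geometry factor.
#'
#' @param freq_hz Frequencies in Hz.
#' @param p A [cole_params()] object.
#' @param scale Multiplicative scaling of the whole impedance (geometry /
#'   electrode-separation factor); default 1.
#' @return Complex vector, one value per frequency.
#' @examples
#' p <- cole_params(100, 20, 1e-4, 1)
#' cole_impedance(1 / (2 * pi * 1e-4), p)  # w * tau = 1
#' @export
cole_impedance <- function(freq_hz, p, scale = 1) {
  stopifnot(inherits(p, "cole_params"), all(freq_hz > 0))
  jwt <- (1i * 2 * pi * freq_hz * p$tau)^p$alpha
  scale * (p$Rinf + (p$R0 - p$Rinf) / (1 + jwt))
}

#' Simulate one noisy bioimpedance spectrum
#'
#' Applies the Cole kernel with size scaling `g(size) = size / reference_size`
#' (impedance grows with electrode separation), then perturbs magnitude with
#' multiplicative log-normal noise and phase with additive Gaussian noise.
#' Phase is clamped to stay non-positive so the spectrum remains capacitive.
#' Uses the current RNG state; seed control is the caller's responsibility.
#'
#' @param p A [cole_params()] object.
#' @param size Fruit maximum diameter in mm; `> 0`.
#' @param grid Frequency grid from [make_frequency_grid()].
#' @param mag_rel_sd Relative (log-scale) sd of the magnitude noise.
#' @param phase_sd_deg Sd in degrees of the additive phase noise.
#' @param reference_size Size (mm) at which `g == 1`.
#' @return Complex vector of impedances, one per grid point.
#' @export
simulate_spectrum <- function(p, size, grid, mag_rel_sd = 0.02,
                              phase_sd_deg = 0.5, reference_size = 25) {
  if (!is.finite(size) || size <= 0) stop("size must be > 0", call. = FALSE)
  stopifnot(mag_rel_sd >= 0, phase_sd_deg >= 0, reference_size > 0)
  z0 <- cole_impedance(grid, p, scale = size / reference_size)
  mag <- Mod(z0) * exp(stats::rnorm(length(grid), 0, mag_rel_sd))
  ph <- Arg(z0) * 180 / pi + stats::rnorm(length(grid), 0, phase_sd_deg)
  ph <- pmin(ph, -1e-6)   # keep a hair below 0 so tan(delta) stays finite
  ph <- pmax(ph, -89.999)
  complex(modulus = mag, argument = ph * pi / 180)
}
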