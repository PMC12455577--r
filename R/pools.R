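#' Lorentzian pool specification
#'
#' One saturation pool modeled as a Lorentzian dip in the Z-spectrum,
#' parameterized by peak depth (amplitude, in normalized-signal units),
#' full width at half maximum (ppm) and resonance center (ppm).
#'
#' @param name pool name; the canonical five-pool model uses
#'   `water`, `MT`, `CR`, `GLU`, `NOE`.
#' @param center_ppm resonance offset (ppm).
#' @param amplitude peak depth, dimensionless, in `[0, 1]`.
#' @param fwhm_ppm full width at half maximum (ppm, > 0).
#' @return a one-row data frame with columns
#'   `name`, `center_ppm`, `amplitude`, `fwhm_ppm`.
#' @export
pool_spec <- function(name, center_ppm, amplitude, fwhm_ppm) {
  if (!is.character(name) || length(name) != 1L)
    stop("name must be a single string")
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be finite and >= 0")
  if (!is.finite(fwhm_ppm) || fwhm_ppm <= 0)
    stop("fwhm_ppm must be finite and > 0")
  if (!is.finite(center_ppm))
    stop("center_ppm must be finite")
  data.frame(name = name, center_ppm = center_ppm,
             amplitude = amplitude, fwhm_ppm = fwhm_ppm,
             stringsAsFactors = FALSE)
}

#' Default five-pool ground-truth table
#'
#' Baseline Lorentzian parameters for the five-pool brain model: water at
#' 0 ppm, a broad magnetization-transfer (MT) pool at -2.5 ppm, creatine
#' (CR) at +2 ppm, glutamate (GLU) at +3 ppm and the nuclear Overhauser
#' effect (NOE) at -3.5 ppm. Amplitudes and widths are representative of
#' mouse brain at high field and serve as the phantom generator's
#' baseline truth.
#'
#' @return data frame of five [pool_spec()] rows.
#' @export
default_pools <- function() {
  rbind(
    pool_spec("water", 0.0, 0.80, 1.4),
    pool_spec("MT",   -2.5, 0.10, 25.0),
    pool_spec("CR",    2.0, 0.02, 0.5),
    pool_spec("GLU",   3.0, 0.03, 1.0),
    pool_spec("NOE",  -3.5, 0.05, 3.0)
  )
}

validate_pools <- function(pools) {
  need <- c("name", "center_ppm", "amplitude", "fwhm_ppm")
  if (!is.data.frame(pools) || !all(need %in% names(pools)))
    stop("pools must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (any(!is.finite(pools$fwhm_ppm)) || any(pools$fwhm_ppm <= 0))
    stop("all pool widths (fwhm_ppm) must be positive")
  if (any(!is.finite(pools$amplitude)) || any(pools$amplitude < 0))
    stop("all pool amplitudes must be >= 0")
  if (anyDuplicated(pools$name))
    stop("duplicate pool names: ",
         paste(unique(pools$name[duplicated(pools$name)]), collapse = ", "))
  invisible(pools)
}

#' Lorentzian absorption line
#'
#' Evaluates one pool's Lorentzian dip
#' \deqn{L(\Delta) = A \frac{(\Gamma/2)^2}{(\Gamma/2)^2 + (\Delta - \delta)^2}}
#' where A is the peak depth, \eqn{\Gamma} the FWHM and \eqn{\delta} the
#' pool center. `delta_ppm` is the saturation offset after any B0-shift
#' subtraction. The value equals A at the center and A/2 at
#' \eqn{\delta \pm \Gamma/2} (the definition of FWHM).
#'
#' @param delta_ppm numeric vector of offsets (ppm), B0-corrected.
#' @param pool a one-row pool data frame ([pool_spec()]) or a list with
#'   `center_ppm`, `amplitude`, `fwhm_ppm`.
#' @return numeric vector of dimensionless absorption values in `[0, A]`.
#' @export
lorentzian_line <- function(delta_ppm, pool) {
  A <- pool$amplitude
  G <- pool$fwhm_ppm
  d0 <- pool$center_ppm
  if (!is.finite(G) || G <= 0) stop("pool fwhm_ppm must be positive")
  if (!is.finite(A) || A < 0) stop("pool amplitude must be >= 0")
  h2 <- (G / 2)^2
  A * h2 / (h2 + (delta_ppm - d0)^2)
}

#' Multi-pool Z-spectrum model
#'
#' The forward model shared by the generator and the fitter:
#' \deqn{Z(\omega) = 1 - \sum_i L_i(\omega)} with each \eqn{L_i} a
#' [lorentzian_line()]. Fitting this model directly to Z (not 1-Z, not an
#' asymmetry) is the convention used throughout the package.
#'
#' @param pools data frame of pools (see [default_pools()]).
#' @param offsets_ppm numeric vector of offsets (ppm).
#' @return numeric vector of model Z values, one per offset.
#' @export
model_zspectrum <- function(pools, offsets_ppm) {
  validate_pools(pools)
  z <- rep(1, length(offsets_ppm))
  for (i in seq_len(nrow(pools)))
    z <- z - lorentzian_line(offsets_ppm, pools[i, ])
  z
}
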