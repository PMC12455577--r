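#' Saturation schedule
#'
#' A saturation schedule records the offset axis and RF saturation
#' parameters that define one Z-spectrum acquisition: the list of
#' chemical-shift offsets (ppm relative to water at 0 ppm, positive =
#' downfield), the continuous-wave saturation amplitude B1 (microtesla)
#' and the saturation duration (seconds).
#'
#' @param offsets_ppm numeric vector of offsets in ppm; must be strictly
#'   increasing (supply unsorted data to [read_cest_study()] instead,
#'   which reorders signal and offsets together).
#' @param b1_uT saturation amplitude in microtesla (> 0).
#' @param t_sat_s saturation duration in seconds (> 0).
#' @return an object of class `saturation_schedule`.
#' @seealso [cest_schedule()], [wassr_schedule()]
#' @export
saturation_schedule <- function(offsets_ppm, b1_uT, t_sat_s) {
  offsets_ppm <- as.numeric(offsets_ppm)
  if (length(offsets_ppm) < 2L || anyNA(offsets_ppm))
    stop("offsets_ppm must be a numeric vector of >= 2 finite values")
  if (any(diff(offsets_ppm) <= 0))
    stop("offsets_ppm must be strictly increasing")
  if (!is.numeric(b1_uT) || length(b1_uT) != 1L || b1_uT <= 0)
    stop("b1_uT must be a single positive number")
  if (!is.numeric(t_sat_s) || length(t_sat_s) != 1L || t_sat_s <= 0)
    stop("t_sat_s must be a single positive number")
  structure(
    list(offsets_ppm = offsets_ppm, b1_uT = b1_uT, t_sat_s = t_sat_s),
    class = "saturation_schedule"
  )
}

#' Default CEST saturation schedule
#'
#' 51 offsets from -5 to +5 ppm in 0.2 ppm steps, 2 uT continuous-wave
#' saturation for 1 s — the acquisition settings the pipeline targets.
#'
#' @return a [saturation_schedule()].
#' @export
cest_schedule <- function() {
  saturation_schedule(seq(-5, 5, by = 0.2), b1_uT = 2, t_sat_s = 1)
}

#' Default WASSR saturation schedule
#'
#' Low-power, narrow-range direct water saturation used for B0 field
#' mapping: -1 to +1 ppm in 0.02 ppm steps at 0.25 uT. WASSR needs only
#' the direct water line, so the power is kept low to avoid broadening
#' and exchange contamination.
#'
#' @return a [saturation_schedule()].
#' @export
wassr_schedule <- function() {
  saturation_schedule(seq(-1, 1, by = 0.02), b1_uT = 0.25, t_sat_s = 0.5)
}

#' @export
print.saturation_schedule <- function(x, ...) {
  o <- x$offsets_ppm
  cat(sprintf(
    "<saturation_schedule> %d offsets, %.3g..%.3g ppm, B1 = %g uT, t_sat = %g s\n",
    length(o), min(o), max(o), x$b1_uT, x$t_sat_s
  ))
  invisible(x)
}
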