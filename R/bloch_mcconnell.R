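#' One pool's physical parameters for Bloch-McConnell simulation
#'
#' Unlike the phenomenological Lorentzian [pool_spec()], this carries the
#' physics: relative proton pool size (water = 1), exchange rate to
#' water (per second), longitudinal and transverse relaxation times, and
#' chemical shift.
#'
#' @param name pool name.
#' @param pool_fraction relative proton pool size in `(0, 1]`; water = 1.
#' @param exchange_rate_hz exchange rate to water, 1/s (0 for water).
#' @param t1_s,t2_s relaxation times (s, > 0).
#' @param chemical_shift_ppm resonance offset from water (ppm).
#' @return one-row data frame.
#' @export
bm_pool <- function(name, pool_fraction, exchange_rate_hz, t1_s, t2_s,
                    chemical_shift_ppm) {
  stopifnot(pool_fraction > 0, pool_fraction <= 1,
            exchange_rate_hz >= 0, t1_s > 0, t2_s > 0)
  data.frame(name = name, pool_fraction = pool_fraction,
             exchange_rate_hz = exchange_rate_hz, t1_s = t1_s, t2_s = t2_s,
             chemical_shift_ppm = chemical_shift_ppm,
             stringsAsFactors = FALSE)
}

#' Default five-pool physics table
#'
#' Representative brain-tissue values at high field for the
#' Bloch-McConnell oracle: water, a semisolid MT pool with very short
#' T2 (broad line), creatine (+2 ppm, intermediate exchange), glutamate
#' (+3 ppm, fast exchange) and a slow-exchanging NOE pool at -3.5 ppm.
#'
#' @return data frame of [bm_pool()] rows (water first).
#' @export
default_bm_physics <- function() {
  rbind(
    bm_pool("water", 1.000,    0, 1.8, 0.060,  0.0),
    bm_pool("MT",    0.005,   40, 1.0, 1e-5,  -2.5),
    bm_pool("CR",    0.005,  500, 1.3, 0.015,  2.0),
    bm_pool("GLU",   0.008, 1500, 1.2, 0.010,  3.0),
    bm_pool("NOE",   0.030,   20, 1.0, 0.010, -3.5)
  )
}

GAMMA_HZ_PER_UT <- 42.577  # 1H gyromagnetic ratio, Hz per microtesla

#' Simulate a Z-spectrum with the Bloch-McConnell equations
#'
#' Physics oracle, independent of the Lorentzian model: propagates the
#' coupled magnetization of all pools under continuous-wave saturation
#' by matrix exponentiation of the Bloch-McConnell generator over the
#' saturation duration, from thermal equilibrium, and reads out
#' Mz(water)/M0 at each offset. Each solute exchanges with water at its
#' `exchange_rate_hz`; back-rates follow detailed balance
#' (k water-to-solute = fraction x k). No readout is simulated.
#'
#' @param physics data frame of [bm_pool()] rows; must contain a pool
#'   named `water` with fraction 1.
#' @param schedule a [saturation_schedule()] (B1 amplitude and duration
#'   are taken from it).
#' @param b0_tesla static field strength; offsets in ppm are converted
#'   to rad/s with the 1H gyromagnetic ratio. Default 7 T (typical
#'   preclinical small-animal scanner).
#' @return numeric vector of Z values, one per schedule offset.
#' @export
simulate_bloch_mcconnell <- function(physics, schedule, b0_tesla = 7) {
  stopifnot(inherits(schedule, "saturation_schedule"), nrow(physics) >= 1)
  iw <- match("water", physics$name)
  if (is.na(iw)) stop("physics must include a water pool")
  if (physics$pool_fraction[iw] != 1)
    stop("water pool_fraction must be 1")
  n <- nrow(physics)
  hz_per_ppm <- GAMMA_HZ_PER_UT * b0_tesla * 1e6 * 1e-6  # Hz per ppm
  w1 <- 2 * pi * GAMMA_HZ_PER_UT * schedule$b1_uT        # rad/s
  r1 <- 1 / physics$t1_s
  r2 <- 1 / physics$t2_s
  f <- physics$pool_fraction
  k_to_w <- physics$exchange_rate_hz
  k_from_w <- f * k_to_w  # detailed balance; 0 for water itself
  k_from_w[iw] <- 0; k_to_w[iw] <- 0
  m0 <- f
  offs <- schedule$offsets_ppm
  z <- numeric(length(offs))
  ix <- function(i) 3 * (i - 1) + 1  # x row of pool i
  for (jo in seq_along(offs)) {
    # pool offset from the RF in rad/s
    dw <- 2 * pi * hz_per_ppm * (physics$chemical_shift_ppm - offs[jo])
    A <- matrix(0, 3 * n + 1, 3 * n + 1)
    for (i in seq_len(n)) {
      xi <- ix(i); yi <- xi + 1; zi <- xi + 2
      ktot <- if (i == iw) sum(k_from_w) else k_to_w[i]
      A[xi, xi] <- -r2[i] - ktot; A[xi, yi] <- -dw[i]
      A[yi, xi] <- dw[i];         A[yi, yi] <- -r2[i] - ktot
      A[yi, zi] <- w1
      A[zi, yi] <- -w1;           A[zi, zi] <- -r1[i] - ktot
      A[zi, 3 * n + 1] <- r1[i] * m0[i]
      if (i == iw) {
        for (j in seq_len(n)[-iw]) {
          xj <- ix(j)
          A[xi, xj] <- k_to_w[j]
          A[xi + 1, xj + 1] <- k_to_w[j]
          A[xi + 2, xj + 2] <- k_to_w[j]
        }
      } else {
        xw <- ix(iw)
        A[xi, xw] <- k_from_w[i]
        A[yi, xw + 1] <- k_from_w[i]
        A[zi, xw + 2] <- k_from_w[i]
      }
    }
    state0 <- c(rbind(0, 0, m0), 1)
    state <- tryCatch(
      as.matrix(Matrix::expm(A * schedule$t_sat_s)) %*% state0,
      error = function(e)
        stop(sprintf("Bloch-McConnell propagation failed at offset %.3f ppm: %s",
                     offs[jo], conditionMessage(e))))
    zval <- state[ix(iw) + 2] / m0[iw]
    if (!is.finite(zval))
      stop(sprintf("Bloch-McConnell propagation returned a non-finite value at offset %.3f ppm",
                   offs[jo]))
    z[jo] <- zval
  }
  z
}
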