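# brute-force symmetry search on a 1e-4 ppm grid: the independent oracle
# for the maximum-symmetry center estimate
brute_force_center <- function(spectrum, offsets, bound = 0.5, step = 1e-4) {
  zfun <- stats::splinefun(offsets, spectrum, method = "fmm")
  cand <- seq(-bound, bound, by = step)
  cost <- vapply(cand, function(c0) {
    m <- 2 * c0 - offsets
    use <- m >= min(offsets) & m <= max(offsets)
    mean((zfun(m[use]) - spectrum[use])^2)
  }, 0)
  cand[which.min(cost)]
}

wassr_line <- function(shift, noise_sd = 0, seed = NULL) {
  simulate_zspectrum(pool_spec("water", 0, 0.9, 0.3), wassr_schedule(),
                     b0_shift_ppm = shift, noise_sd = noise_sd, seed = seed)
}

test_that("a symmetric line centered at zero yields a zero shift exactly", {
  sw <- wassr_schedule()
  est <- estimate_b0_mscf(wassr_line(0), sw$offsets_ppm)
  expect_equal(est$quality, "ok")
  expect_lt(abs(est$shift_ppm), 1e-6)
})

test_that("MSCF matches the brute-force fine-grid oracle on a shifted line", {
  sw <- wassr_schedule()
  for (shift in c(0.10, -0.27)) {
    z <- wassr_line(shift)
    est <- estimate_b0_mscf(z, sw$offsets_ppm)
    oracle <- brute_force_center(z, sw$offsets_ppm)
    expect_equal(est$quality, "ok")
    expect_lt(abs(est$shift_ppm - shift), 0.01)
    expect_lt(abs(est$shift_ppm - oracle), 0.005)
  }
})

test_that("degenerate spectra are flagged failed, not guessed", {
  sw <- wassr_schedule()
  flat <- rep(1, length(sw$offsets_ppm))
  est <- estimate_b0_mscf(flat, sw$offsets_ppm)
  expect_equal(est$quality, "failed")
  expect_true(is.na(est$shift_ppm))
  expect_error(estimate_b0_mscf(c(1, 0.5, 1), c(-1, 0, 1)), "7")
})

test_that("mirroring the spectrum negates the estimated shift", {
  sw <- wassr_schedule()
  for (shift in c(0.08, 0.21)) {
    z <- wassr_line(shift)
    zm <- rev(z)  # offsets are symmetric, so this mirrors the line
    a <- estimate_b0_mscf(z, sw$offsets_ppm)$shift_ppm
    b <- estimate_b0_mscf(zm, sw$offsets_ppm)$shift_ppm
    expect_equal(a, -b, tolerance = 1e-6)
  }
})

test_that("field-map RMSE does not improve as noise grows", {
  sw <- wassr_schedule()
  shifts <- seq(-0.3, 0.3, length.out = 25)
  rmse <- vapply(c(0, 0.005, 0.02), function(ns) {
    errs <- vapply(seq_along(shifts), function(i) {
      z <- wassr_line(shifts[i], noise_sd = ns, seed = 1000L + i)
      estimate_b0_mscf(z, sw$offsets_ppm)$shift_ppm - shifts[i]
    }, 0)
    sqrt(mean(errs^2))
  }, 0)
  expect_true(all(diff(rmse) >= 0))
})

test_that("build_field_map recovers a smooth field and flags out-of-range voxels", {
  lay <- default_roi_layout(small_grid)
  mask <- lay$labels > 0L
  field <- cestz:::smooth_b0_field(small_grid, 0.3, seed = 5L)
  st <- generate_wassr_stack(field, wassr_schedule(), mask = mask)
  fm <- suppressMessages(build_field_map(st, mask))
  err <- abs(fm$shift_ppm[mask] - field[mask])
  expect_lt(max(err), 0.01)
  expect_true(all(fm$quality[mask] == "ok"))
  # a zero field maps to (numerically) zero everywhere
  st0 <- generate_wassr_stack(matrix(0, 16, 16), wassr_schedule(), mask = mask)
  fm0 <- suppressMessages(build_field_map(st0, mask))
  expect_lt(max(abs(fm0$shift_ppm[mask])), 0.01)
  # true shift beyond the WASSR range -> edge flag
  fbig <- field; fbig[which(mask)[1]] <- 1.4
  stb <- suppressWarnings(generate_wassr_stack(fbig, wassr_schedule(), mask = mask))
  fmb <- suppressMessages(build_field_map(stb, mask))
  expect_equal(fmb$quality[which(mask)[1]], "edge")
})

test_that("correct_spectrum is the identity at zero shift and shifts by whole grid steps exactly", {
  sched <- cest_schedule()
  z <- simulate_zspectrum(default_pools(), sched)
  expect_identical(correct_spectrum(z, sched$offsets_ppm, 0), z)
  # one grid step: interior output equals the input shifted by one index
  zc <- correct_spectrum(z, sched$offsets_ppm, 0.2)
  n <- length(z)
  expect_equal(zc[1:(n - 1)], z[2:n], tolerance = 1e-12)
  expect_true(is.na(zc[n]))  # source beyond the acquired range: dropped
})

test_that("shift-then-correct round trip restores the unshifted spectrum", {
  sched <- cest_schedule()
  ref <- simulate_zspectrum(default_pools(), sched)
  for (s in c(0.13, -0.31)) {
    z <- simulate_zspectrum(default_pools(), sched, b0_shift_ppm = s)
    zc <- correct_spectrum(z, sched$offsets_ppm, s)
    interior <- which(abs(sched$offsets_ppm) <= 4.5 & is.finite(zc))
    expect_gt(length(interior), 40L)
    expect_lt(max(abs(zc[interior] - ref[interior])), 1e-3)
  }
})

test_that("failed shifts disable the voxel instead of silently passing data through", {
  sched <- cest_schedule()
  z <- simulate_zspectrum(default_pools(), sched)
  expect_true(all(is.na(correct_spectrum(z, sched$offsets_ppm, NA_real_))))
  expect_error(correct_spectrum(z, sched$offsets_ppm, 6), "half")
})
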