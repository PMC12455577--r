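test_that("full-line AUC has its closed form and both conventions are linear in amplitude", {
  p <- pool_spec("GLU", 3, 0.1, 1.0)
  expect_equal(pool_auc(p), 0.05 * pi)
  expect_equal(pool_auc(pool_spec("GLU", 3, 0, 1)), 0)
  expect_equal(pool_auc(pool_spec("GLU", 3, 0, 1), "numeric_window",
                        c(-5, 5)), 0)
  # exact linearity under both conventions
  for (scale in c(0.5, 2, 7)) {
    ps <- p; ps$amplitude <- p$amplitude * scale
    expect_identical(pool_auc(ps), scale * pool_auc(p))
    expect_equal(pool_auc(ps, "numeric_window", c(-5, 5)),
                 scale * pool_auc(p, "numeric_window", c(-5, 5)),
                 tolerance = 1e-15)
  }
  expect_warning(pool_auc(p, "numeric_window", c(-5, 2)), "center")
})

test_that("windowed AUC agrees with adaptive quadrature of the Lorentzian", {
  p <- pool_spec("GLU", 3, 0.1, 1.0)
  quad <- stats::integrate(function(x) lorentzian_line(x, p), -5, 5,
                           rel.tol = 1e-12)$value
  closed <- pool_auc(p, "numeric_window", c(-5, 5))
  expect_lt(abs(closed - quad) / quad, 1e-8)
})

test_that("noiseless five-pool spectra are recovered to fractions of a percent", {
  sched <- cest_schedule()
  truth <- default_pools()
  z <- simulate_zspectrum(truth, sched)
  fr <- fit_voxel(z, sched$offsets_ppm)
  expect_true(fr$converged)
  expect_rel_equal(fr$pools$amplitude, truth$amplitude, 0.01)
  expect_rel_equal(fr$pools$fwhm_ppm, truth$fwhm_ppm, 0.02)
  expect_lt(max(abs(fr$pools$center_ppm - truth$center_ppm)), 0.02)
})

test_that("a flat spectrum drives every CEST-pool amplitude to zero", {
  sched <- cest_schedule()
  fr <- fit_voxel(rep(1, 51), sched$offsets_ppm)
  cest_pools <- fr$pools$name %in% c("CR", "GLU", "NOE", "MT")
  expect_true(all(fr$pools$amplitude[cest_pools] < 1e-6))
})

test_that("a water-only spectrum leaves the solute pools empty", {
  sched <- cest_schedule()
  water <- pool_spec("water", 0, 0.8, 1.4)
  z <- simulate_zspectrum(water, sched)
  fr <- fit_voxel(z, sched$offsets_ppm)
  solutes <- fr$pools$name %in% c("CR", "GLU", "NOE")
  expect_true(all(fr$pools$amplitude[solutes] < 1e-3))
  expect_rel_equal(fr$pools$amplitude[fr$pools$name == "water"], 0.8, 0.01)
})

test_that("the optimizer never worsens the initialization and skips starved voxels", {
  sched <- cest_schedule()
  set.seed(21)
  for (i in 1:20) {
    z <- simulate_zspectrum(default_pools(), sched, noise_sd = 0.01)
    fr <- fit_voxel(z, sched$offsets_ppm)
    expect_lte(fr$deviance, fr$init_deviance)
  }
  # too few usable offsets
  z <- simulate_zspectrum(default_pools(), sched)
  z[11:51] <- NA
  expect_error(fit_voxel(z, sched$offsets_ppm), "usable offsets")
  expect_null(fit_voxel(rep(NA_real_, 51), sched$offsets_ppm))
})

test_that("a coarse grid search over the GLU parameters lands on the fitted optimum", {
  sched <- cest_schedule()
  truth <- default_pools()
  a_grid <- seq(0.01, 0.06, by = 0.005)
  g_grid <- seq(0.6, 1.4, by = 0.1)
  set.seed(4)
  amps <- stats::runif(20, 0.015, 0.03)  # GLU amplitudes across 'voxels'
  for (a_true in amps) {
    pools <- truth; pools$amplitude[pools$name == "GLU"] <- a_true
    z <- simulate_zspectrum(pools, sched)
    fr <- fit_voxel(z, sched$offsets_ppm, quick_fit_config())
    # brute-force oracle: grid over (A_GLU, FWHM_GLU), other pools at truth
    cost <- outer(a_grid, g_grid, Vectorize(function(a, g) {
      p <- pools
      p$amplitude[p$name == "GLU"] <- a
      p$fwhm_ppm[p$name == "GLU"] <- g
      sum((z - model_zspectrum(p, sched$offsets_ppm))^2)
    }))
    best <- which(cost == min(cost), arr.ind = TRUE)[1, ]
    fit_a <- fr$pools$amplitude[fr$pools$name == "GLU"]
    fit_g <- fr$pools$fwhm_ppm[fr$pools$name == "GLU"]
    expect_lte(abs(a_grid[best[1]] - fit_a), 0.005 + 1e-9)
    expect_lte(abs(g_grid[best[2]] - fit_g), 0.1 + 1e-9)
  }
})

test_that("GLU amplitude errors track the information bound and shrink with noise", {
  rec <- recover_parameters(noise_sds = c(0, 0.002, 0.005), n_rep = 70L,
                            b0_range_ppm = 0, seed = 99L)
  glu <- rec$summary[rec$summary$pool == "GLU", ]
  glu <- glu[order(glu$noise_sd), ]
  # Cramer-Rao bound for the 15-parameter fit at noise_sd 0.005 puts the
  # GLU amplitude sd at ~0.005 (17% of the 0.03 truth), i.e. a
  # half-normal median |relative error| floor of ~11%. The fitter should
  # sit near that floor, not far above it.
  sched <- cest_schedule()
  par_truth <- cestz:::fit_par_vectors(fit_config())$init
  J <- cestz:::zmodel_jac(par_truth, sched$offsets_ppm)
  crlb_sd <- 0.005 * sqrt(solve(t(J) %*% J)[10, 10])
  floor_median <- stats::qnorm(0.75) * crlb_sd / 0.03
  expect_lt(glu$median_abs_rel_err[glu$noise_sd == 0.005], 1.5 * floor_median)
  expect_true(all(diff(glu$median_abs_rel_err) >= 0))
})

test_that("fit_stack corrects, fits and maps AUC within tolerance of the truth", {
  cfg <- small_phantom_config(noise_sd = 0, b0_amplitude_ppm = 0.1, seed = 2L)
  st <- generate_phantom_study(cfg)
  s <- st$subjects[[1]]
  stack <- normalize_stack(s$cest)
  fm <- suppressMessages(build_field_map(s$wassr, stack$mask))
  maps <- fit_stack(stack, fm, quick_fit_config())
  mask <- stack$mask
  expect_gte(mean(maps$converged[mask]), 0.99)
  # GLU AUC within 2% of ground truth wherever converged
  truth_auc <- matrix(NA_real_, 16, 16)
  for (r in unname(st$labels$legend)) {
    vox <- cestz:::region_voxels(st$labels, r)
    tr <- st$truth
    row <- tr[tr$subject_id == s$id & tr$region == r & tr$pool == "GLU", ]
    truth_auc[vox] <- row$auc
  }
  conv <- maps$converged & mask
  rel <- abs(maps$auc$GLU[conv] / truth_auc[conv] - 1)
  expect_lt(max(rel), 0.02)
})

test_that("with a zero field the correction stage is a no-op for the maps", {
  cfg <- small_phantom_config(noise_sd = 0, b0_amplitude_ppm = 0, seed = 2L)
  st <- generate_phantom_study(cfg)
  s <- st$subjects[[1]]
  stack <- normalize_stack(s$cest)
  fm <- suppressMessages(build_field_map(s$wassr, stack$mask))
  qc <- quick_fit_config()
  with_corr <- fit_stack(stack, fm, qc)
  without <- fit_stack(stack, NULL, qc)
  for (p in names(with_corr$auc))
    expect_equal(with_corr$auc[[p]], without$auc[[p]], tolerance = 1e-6)
})

test_that("an amplitude effect propagates linearly into the fitted AUC ratio", {
  cfg <- small_phantom_config(
    noise_sd = 0, b0_amplitude_ppm = 0,
    n_per_group = 1L,
    effects = data.frame(group = "ART", region = "thalamus", pool = "GLU",
                         factor = 0.7))
  st <- generate_phantom_study(cfg)
  qc <- quick_fit_config()
  maps <- lapply(st$subjects, function(s)
    fit_stack(normalize_stack(s$cest), NULL, qc))
  names(maps) <- vapply(st$subjects, `[[`, "", "id")
  tab <- aggregate_roi(maps, st$labels, st$design)
  th_glu <- tab[tab$region == "thalamus" & tab$pool == "GLU", ]
  ratio <- th_glu$value[th_glu$group == "ART"] /
    th_glu$value[th_glu$group == "vehicle"]
  expect_gt(ratio, 0.65); expect_lt(ratio, 0.75)
})

test_that("fit configuration rejects inconsistent bounds", {
  pools <- default_fit_pools()
  pools$amp_init[1] <- 2
  expect_error(fit_config(pools), "amplitude bounds")
  pools <- default_fit_pools()
  pools$fwhm_lo[2] <- -1
  expect_error(fit_config(pools), "width bounds")
})
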