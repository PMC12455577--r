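#' Simulate one Z-spectrum
#'
#' Generative counterpart of [model_zspectrum()]: evaluates
#' \eqn{Z(\omega) = 1 - \sum_i L_i(\omega - \delta B_0) + \epsilon} over a
#' saturation schedule, where \eqn{\delta B_0} shifts the whole spectrum
#' along the offset axis (field inhomogeneity) and \eqn{\epsilon} is
#' optional noise on the normalized signal.
#'
#' @param pools data frame of Lorentzian pools (see [default_pools()]).
#' @param schedule a [saturation_schedule()].
#' @param b0_shift_ppm scalar field shift applied to the whole spectrum.
#' @param noise_sd standard deviation of the noise on the normalized
#'   signal (0 for noiseless).
#' @param seed optional integer seed for the noise draw.
#' @param noise_model `"gaussian"` (additive, the default) or `"rician"`
#'   (magnitude of the noisy complex signal, relevant at low SNR).
#' @param strict if `TRUE`, error when pool amplitudes sum above 1
#'   (which lets noiseless Z go negative); default warns.
#' @return numeric vector of Z values, one per schedule offset.
#' @export
simulate_zspectrum <- function(pools, schedule, b0_shift_ppm = 0,
                               noise_sd = 0, seed = NULL,
                               noise_model = c("gaussian", "rician"),
                               strict = FALSE) {
  validate_pools(pools)
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(schedule, "saturation_schedule"),
            is.finite(b0_shift_ppm), noise_sd >= 0)
  if (nrow(pools) == 0L) stop("pools must be non-empty")
  if (sum(pools$amplitude) > 1) {
    msg <- sprintf("pool amplitudes sum to %.3f > 1; Z may go negative",
                   sum(pools$amplitude))
    if (strict) stop(msg) else warning(msg)
  }
  z <- model_zspectrum(pools, schedule$offsets_ppm - b0_shift_ppm)
  add_signal_noise(z, noise_sd, seed, noise_model)
}

add_signal_noise <- function(z, noise_sd, seed = NULL,
                             noise_model = "gaussian") {
  if (noise_sd == 0) return(z)
  if (!is.null(seed)) set.seed(seed)
  if (noise_model == "gaussian") {
    z + stats::rnorm(length(z), 0, noise_sd)
  } else {
    sqrt((z + stats::rnorm(length(z), 0, noise_sd))^2 +
           stats::rnorm(length(z), 0, noise_sd)^2)
  }
}

# Noiseless Z for many voxels at once: offsets x voxels matrix.
# Voxel i's spectrum is the pool model evaluated at offsets - shift[i].
zspec_matrix <- function(pools, offsets_ppm, shifts_ppm) {
  n_off <- length(offsets_ppm)
  n_vox <- length(shifts_ppm)
  z <- matrix(1, n_off, n_vox)
  for (i in seq_len(nrow(pools))) {
    A <- pools$amplitude[i]
    h2 <- (pools$fwhm_ppm[i] / 2)^2
    d <- outer(offsets_ppm - pools$center_ppm[i], shifts_ppm, "-")
    z <- z - A * h2 / (h2 + d^2)
  }
  z
}

#' Default ROI layout
#'
#' Builds the phantom's region label map on an `nx` by `ny` grid:
#' a central thalamus, paired hippocampal and piriform-cortex patches,
#' and a cortical rim, all inside an elliptical brain outline. Labels:
#' 1 = cortex, 2 = hippocampus, 3 = piriform_cortex, 4 = thalamus;
#' 0 = background. The whole-brain region is always derived downstream
#' as the union of the labeled voxels, never stored.
#'
#' @param grid_shape integer vector `c(nx, ny)`.
#' @return a `roi_label_map`: list with integer matrix `labels` and named
#'   `legend` mapping label integers to region names.
#' @export
default_roi_layout <- function(grid_shape = c(64L, 64L)) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  u <- matrix(rep((seq_len(nx) - (nx + 1) / 2) / (nx / 2), ny), nx, ny)
  v <- matrix(rep((seq_len(ny) - (ny + 1) / 2) / (ny / 2), each = nx), nx, ny)
  in_ell <- function(cu, cv, au, av) ((u - cu) / au)^2 + ((v - cv) / av)^2 <= 1
  brain <- in_ell(0, 0, 0.92, 0.80)
  rim <- brain & !in_ell(0, 0, 0.70, 0.58)
  thal <- in_ell(0, 0.10, 0.30, 0.22)
  hip <- in_ell(-0.36, -0.22, 0.22, 0.18) | in_ell(0.36, -0.22, 0.22, 0.18)
  pir <- in_ell(-0.52, 0.42, 0.20, 0.20) | in_ell(0.52, 0.42, 0.20, 0.20)
  labels <- matrix(0L, nx, ny)
  labels[rim] <- 1L
  labels[pir & brain] <- 3L
  labels[hip] <- 2L
  labels[thal] <- 4L
  roi_label_map(labels,
                legend = c("1" = "cortex", "2" = "hippocampus",
                           "3" = "piriform_cortex", "4" = "thalamus"))
}

#' Phantom study configuration
#'
#' Describes one complete in-silico CEST study: grid, ROI layout, group
#' design, baseline pools, region- and group-specific effects, B0
#' inhomogeneity, and noise. The defaults emulate the target experiment:
#' four groups (vehicle, ART, nicotine, cotreat) of four subjects each,
#' a 64 x 64 single slice, 51-offset CEST schedule, and treatment
#' effects of lower thalamic glutamate amplitude (x0.7 in all three
#' treatment groups) plus higher hippocampal NOE amplitude (x1.3 in the
#' co-treatment group).
#'
#' @param grid_shape `c(nx, ny)` voxel grid.
#' @param roi_layout a `roi_label_map`; default [default_roi_layout()].
#' @param groups character vector of group names.
#' @param n_per_group subjects per group.
#' @param baseline_pools data frame of baseline pools.
#' @param effects data frame with columns `group`, `region`, `pool`,
#'   `factor`: multiplicative amplitude factors (> 0) applied to the
#'   baseline pool amplitude in that region for that group. Default:
#'   [default_effects()] restricted to the groups present; use
#'   [null_effects()] for a null phantom.
#' @param b0_amplitude_ppm maximum absolute value of the smooth per-voxel
#'   B0 field (ppm).
#' @param noise_sd noise standard deviation on the normalized signal.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param schedule CEST [saturation_schedule()].
#' @param wassr_sched WASSR [saturation_schedule()].
#' @param wassr_water water pool used for the WASSR direct-saturation
#'   line (narrow, low-power regime).
#' @param reference_value unsaturated signal S0 (arbitrary units).
#' @param seed root integer seed; per-subject seeds are derived from it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L),
                           roi_layout = default_roi_layout(grid_shape),
                           groups = c("vehicle", "ART", "nicotine", "cotreat"),
                           n_per_group = 4L,
                           baseline_pools = default_pools(),
                           effects = NULL,
                           b0_amplitude_ppm = 0.1,
                           noise_sd = 0.005,
                           noise_model = "gaussian",
                           schedule = cest_schedule(),
                           wassr_sched = wassr_schedule(),
                           wassr_water = pool_spec("water", 0, 0.9, 0.3),
                           reference_value = 1000,
                           seed = 1L) {
  validate_pools(baseline_pools)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 8L),
            n_per_group >= 1L, length(groups) >= 2L,
            b0_amplitude_ppm >= 0, noise_sd >= 0, reference_value > 0)
  if (!inherits(roi_layout, "roi_label_map"))
    stop("roi_layout must be a roi_label_map")
  if (!all(dim(roi_layout$labels) == grid_shape))
    stop("roi_layout grid does not match grid_shape")
  if (is.null(effects)) {
    effects <- default_effects()
    effects <- effects[effects$group %in% groups &
                         effects$region %in% unname(roi_layout$legend), ]
  }
  effects <- as.data.frame(effects)
  if (nrow(effects) > 0) {
    need <- c("group", "region", "pool", "factor")
    if (!all(need %in% names(effects)))
      stop("effects needs columns ", paste(need, collapse = ", "))
    if (any(effects$factor <= 0)) stop("effect factors must be > 0")
    bad_region <- setdiff(effects$region, unname(roi_layout$legend))
    if (length(bad_region))
      stop("effects name regions absent from roi_layout: ",
           paste(bad_region, collapse = ", "))
    bad_group <- setdiff(effects$group, groups)
    if (length(bad_group))
      stop("effects name unknown groups: ", paste(bad_group, collapse = ", "))
    bad_pool <- setdiff(effects$pool, baseline_pools$name)
    if (length(bad_pool))
      stop("effects name unknown pools: ", paste(bad_pool, collapse = ", "))
  }
  structure(list(
    grid_shape = as.integer(grid_shape), roi_layout = roi_layout,
    groups = groups, n_per_group = as.integer(n_per_group),
    baseline_pools = baseline_pools, effects = effects,
    b0_amplitude_ppm = b0_amplitude_ppm, noise_sd = noise_sd,
    noise_model = noise_model, schedule = schedule,
    wassr_sched = wassr_sched, wassr_water = wassr_water,
    reference_value = reference_value, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Default group x region x pool effects
#'
#' Lower thalamic GLU amplitude in every treatment group (factor 0.7)
#' and higher hippocampal NOE amplitude under co-treatment (factor 1.3).
#'
#' @return effects data frame for [phantom_config()].
#' @export
default_effects <- function() {
  data.frame(
    group = c("ART", "nicotine", "cotreat", "cotreat"),
    region = c("thalamus", "thalamus", "thalamus", "hippocampus"),
    pool = c("GLU", "GLU", "GLU", "NOE"),
    factor = c(0.7, 0.7, 0.7, 1.3),
    stringsAsFactors = FALSE
  )
}

#' Null effects (all factors 1)
#' @return empty effects data frame (no group differs from baseline).
#' @export
null_effects <- function() {
  data.frame(group = character(), region = character(),
             pool = character(), factor = numeric(),
             stringsAsFactors = FALSE)
}

# Smooth low-order 2-D field with subject-specific random coefficients,
# scaled so max |field| over the grid equals amplitude_ppm.
smooth_b0_field <- function(grid_shape, amplitude_ppm, seed) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  if (amplitude_ppm == 0) return(matrix(0, nx, ny))
  set.seed(seed)
  cf <- stats::rnorm(5)
  u <- matrix(rep((seq_len(nx) - (nx + 1) / 2) / (nx / 2), ny), nx, ny)
  v <- matrix(rep((seq_len(ny) - (ny + 1) / 2) / (ny / 2), each = nx), nx, ny)
  f <- cf[1] * u + cf[2] * v + cf[3] * u * v +
    cf[4] * (u^2 - v^2) + cf[5] * (u^2 + v^2 - 1)
  f / max(abs(f)) * amplitude_ppm
}

#' Generate a WASSR stack over a B0 field
#'
#' Per voxel, a water-only direct-saturation spectrum centered at that
#' voxel's field shift, sampled on the WASSR schedule. Voxels whose true
#' shift falls outside the schedule's offset range are flagged `edge`
#' (their minimum cannot be bracketed) with a warning.
#'
#' @param field_map_ppm numeric matrix of per-voxel B0 shifts (ppm).
#' @param schedule_wassr WASSR [saturation_schedule()]; must span the
#'   field map's shift range.
#' @param water_pool water [pool_spec()] for the direct-saturation line.
#' @param noise_sd noise SD on the normalized signal.
#' @param seed optional seed.
#' @param mask optional logical matrix; spectra are only generated
#'   inside it (default: everywhere).
#' @return list with `signal` (array nx x ny x n_offsets), `edge`
#'   (logical matrix) and `schedule`.
#' @export
generate_wassr_stack <- function(field_map_ppm, schedule_wassr,
                                 water_pool = pool_spec("water", 0, 0.9, 0.3),
                                 noise_sd = 0, seed = NULL, mask = NULL) {
  stopifnot(is.matrix(field_map_ppm),
            inherits(schedule_wassr, "saturation_schedule"))
  offs <- schedule_wassr$offsets_ppm
  if (is.null(mask)) mask <- matrix(TRUE, nrow(field_map_ppm), ncol(field_map_ppm))
  edge <- mask & (field_map_ppm < min(offs) | field_map_ppm > max(offs))
  if (any(edge))
    warning(sprintf("%d voxel(s) have B0 shifts outside the WASSR range; flagged edge",
                    sum(edge)))
  shifts <- field_map_ppm[mask]
  zm <- zspec_matrix(water_pool, offs, shifts)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    zm <- zm + matrix(stats::rnorm(length(zm), 0, noise_sd), nrow(zm))
  }
  sig <- array(NA_real_, c(dim(field_map_ppm), length(offs)))
  idx <- which(mask)
  for (j in seq_along(offs)) {
    plane <- matrix(NA_real_, nrow(field_map_ppm), ncol(field_map_ppm))
    plane[idx] <- zm[j, ]
    sig[, , j] <- plane
  }
  list(signal = sig, edge = edge, schedule = schedule_wassr)
}

# Per-subject ground-truth pools: baseline amplitudes scaled by the
# (group, region, pool) effect factors.
region_pools <- function(config, group) {
  regions <- unname(config$roi_layout$legend)
  out <- list()
  for (r in regions) {
    p <- config$baseline_pools
    e <- config$effects
    if (nrow(e) > 0) {
      sel <- e$group == group & e$region == r
      for (k in which(sel)) {
        i <- match(e$pool[k], p$name)
        p$amplitude[i] <- p$amplitude[i] * e$factor[k]
      }
    }
    out[[r]] <- p
  }
  out
}

subject_seeds <- function(root_seed, n) {
  set.seed(root_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a complete phantom study
#'
#' Produces the full in-silico study bundle: per subject a CEST stack,
#' WASSR stack, reference (S0) image and B0 truth field; plus the shared
#' label map, the subject-to-group design table and a ground-truth
#' parameter table (per subject x region x pool: amplitude, width,
#' center, full-line AUC). Pools are constant within a region: the
#' baseline pool table scaled by the configured (group, region, pool)
#' amplitude factors. Deterministic given `config$seed`.
#'
#' @param config a [phantom_config()].
#' @return a `phantom_study` list: `subjects` (each with `id`, `group`,
#'   `cest` ([zspec_stack()] of raw signal with reference), `wassr`,
#'   `b0_truth`), `labels`, `design`, `truth`, `config`.
#' @export
generate_phantom_study <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop("config must be a phantom_config")
  labels <- config$roi_layout
  mask <- labels$labels > 0L
  design <- data.frame(
    subject_id = sprintf("sub-%02d", seq_len(length(config$groups) * config$n_per_group)),
    group = rep(config$groups, each = config$n_per_group),
    stringsAsFactors = FALSE
  )
  seeds <- subject_seeds(config$seed, nrow(design) * 3L)
  offs <- config$schedule$offsets_ppm
  truth_rows <- list()
  subjects <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    grp <- design$group[s]
    b0 <- smooth_b0_field(config$grid_shape, config$b0_amplitude_ppm,
                          seeds[3 * s - 2])
    pools_by_region <- region_pools(config, grp)
    z <- array(NA_real_, c(config$grid_shape, length(offs)))
    idx_all <- integer(0); zm_all <- NULL
    for (r in names(pools_by_region)) {
      lab <- as.integer(names(config$roi_layout$legend)[
        match(r, unname(config$roi_layout$legend))])
      idx <- which(labels$labels == lab)
      if (!length(idx)) next
      zm <- zspec_matrix(pools_by_region[[r]], offs, b0[idx])
      idx_all <- c(idx_all, idx)
      zm_all <- if (is.null(zm_all)) zm else cbind(zm_all, zm)
      p <- pools_by_region[[r]]
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject_id = design$subject_id[s], group = grp, region = r,
        pool = p$name, amplitude = p$amplitude, fwhm_ppm = p$fwhm_ppm,
        center_ppm = p$center_ppm,
        auc = p$amplitude * p$fwhm_ppm * pi / 2,
        stringsAsFactors = FALSE
      )
    }
    if (config$noise_sd > 0) {
      set.seed(seeds[3 * s - 1])
      if (config$noise_model == "gaussian") {
        zm_all <- zm_all + matrix(stats::rnorm(length(zm_all), 0, config$noise_sd),
                                  nrow(zm_all))
      } else {
        zm_all <- sqrt((zm_all + matrix(stats::rnorm(length(zm_all), 0, config$noise_sd),
                                        nrow(zm_all)))^2 +
                         matrix(stats::rnorm(length(zm_all), 0, config$noise_sd),
                                nrow(zm_all))^2)
      }
    }
    for (j in seq_along(offs)) {
      plane <- matrix(NA_real_, config$grid_shape[1], config$grid_shape[2])
      plane[idx_all] <- zm_all[j, ]
      z[, , j] <- plane
    }
    reference <- matrix(config$reference_value,
                        config$grid_shape[1], config$grid_shape[2])
    raw <- z * config$reference_value
    wassr <- generate_wassr_stack(b0, config$wassr_sched, config$wassr_water,
                                  noise_sd = config$noise_sd,
                                  seed = seeds[3 * s], mask = mask)
    subjects[[s]] <- list(
      id = design$subject_id[s], group = grp,
      cest = zspec_stack(raw, offs, mask = mask, reference = reference,
                         normalized = FALSE, schedule = config$schedule),
      wassr = wassr, b0_truth = b0
    )
  }
  structure(list(subjects = subjects, labels = labels, design = design,
                 truth = do.call(rbind, truth_rows), config = config),
            class = "phantom_study")
}
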