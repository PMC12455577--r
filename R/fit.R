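#' Fitting configuration for the five-pool decomposition
#'
#' Per-pool initialization and box bounds for amplitude and width, plus
#' a center slack around each pool's nominal resonance, and optimizer
#' settings. The defaults (amplitude init and `[lo, hi]`; FWHM init and
#' `[lo, hi]` in ppm; center slack in ppm):
#' water 0.8, `[0.02, 1]`, 1.4, `[0.3, 10]`, 0.2;
#' MT 0.1, `[0, 0.5]`, 25, `[10, 100]`, 2 at -2.5 ppm;
#' CR 0.02, `[0, 0.3]`, 0.5, `[0.2, 3]`, 0.1 at +2 ppm;
#' GLU 0.03, `[0, 0.3]`, 1.0, `[0.2, 3]`, 0.1 at +3 ppm;
#' NOE 0.05, `[0, 0.5]`, 3.0, `[0.5, 8]`, 0.2 at -3.5 ppm.
#'
#' @param pools data frame with columns `name`, `center_ppm`,
#'   `amp_init`, `amp_lo`, `amp_hi`, `fwhm_init`, `fwhm_lo`, `fwhm_hi`,
#'   `center_slack_ppm`.
#' @param max_iterations Levenberg-Marquardt iteration cap.
#' @param multistart number of starts: the nominal initialization plus
#'   `multistart - 1` restarts with amplitude inits jittered by up to
#'   +/-50% (seeded); best deviance wins, ties broken by iteration count.
#' @param ftol,ptol optimizer convergence tolerances.
#' @param min_offsets minimum usable offsets per voxel.
#' @param seed seed for the multistart jitter.
#' @return a `fit_config` list.
#' @export
fit_config <- function(pools = default_fit_pools(),
                       max_iterations = 300L, multistart = 3L,
                       ftol = 1e-10, ptol = 1e-10,
                       min_offsets = 20L, seed = 1L) {
  need <- c("name", "center_ppm", "amp_init", "amp_lo", "amp_hi",
            "fwhm_init", "fwhm_lo", "fwhm_hi", "center_slack_ppm")
  if (!is.data.frame(pools) || !all(need %in% names(pools)))
    stop("pools must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(pools$name)) stop("duplicate pool names in fit config")
  with(pools, {
    if (any(amp_lo < 0 | amp_hi > 1 | amp_init < amp_lo | amp_init > amp_hi))
      stop("amplitude bounds must lie in [0, 1] and contain the initialization")
    if (any(fwhm_lo <= 0 | fwhm_init < fwhm_lo | fwhm_init > fwhm_hi))
      stop("width bounds must be positive and contain the initialization")
    if (any(center_slack_ppm < 0)) stop("center slack must be >= 0")
  })
  structure(list(pools = pools, max_iterations = as.integer(max_iterations),
                 multistart = as.integer(multistart), ftol = ftol,
                 ptol = ptol, min_offsets = as.integer(min_offsets),
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Default per-pool initialization/bounds table
#' @return data frame consumed by [fit_config()].
#' @export
default_fit_pools <- function() {
  data.frame(
    name = c("water", "MT", "CR", "GLU", "NOE"),
    center_ppm = c(0, -2.5, 2, 3, -3.5),
    amp_init = c(0.8, 0.1, 0.02, 0.03, 0.05),
    amp_lo = c(0.02, 0, 0, 0, 0),
    amp_hi = c(1, 0.5, 0.3, 0.3, 0.5),
    fwhm_init = c(1.4, 25, 0.5, 1, 3),
    fwhm_lo = c(0.3, 10, 0.2, 0.2, 0.5),
    fwhm_hi = c(10, 100, 3, 3, 8),
    center_slack_ppm = c(0.2, 2, 0.1, 0.1, 0.2),
    stringsAsFactors = FALSE
  )
}

# parameter vector layout: (A_i, G_i, C_i) per pool, config order
fit_par_vectors <- function(config) {
  p <- config$pools
  n <- nrow(p)
  init <- lo <- hi <- numeric(3 * n)
  for (i in seq_len(n)) {
    j <- 3 * (i - 1)
    init[j + 1] <- p$amp_init[i];  lo[j + 1] <- p$amp_lo[i];  hi[j + 1] <- p$amp_hi[i]
    init[j + 2] <- p$fwhm_init[i]; lo[j + 2] <- p$fwhm_lo[i]; hi[j + 2] <- p$fwhm_hi[i]
    init[j + 3] <- p$center_ppm[i]
    lo[j + 3] <- p$center_ppm[i] - p$center_slack_ppm[i]
    hi[j + 3] <- p$center_ppm[i] + p$center_slack_ppm[i]
  }
  list(init = init, lo = lo, hi = hi)
}

zmodel_par <- function(par, w) {
  z <- rep(1, length(w))
  for (i in seq_len(length(par) / 3)) {
    j <- 3 * (i - 1)
    h2 <- (par[j + 2] / 2)^2
    z <- z - par[j + 1] * h2 / (h2 + (w - par[j + 3])^2)
  }
  z
}

# Jacobian of the residual (obs - model) w.r.t. the parameter vector
zmodel_jac <- function(par, w) {
  n <- length(par) / 3
  J <- matrix(0, length(w), length(par))
  for (i in seq_len(n)) {
    j <- 3 * (i - 1)
    A <- par[j + 1]; G <- par[j + 2]; C <- par[j + 3]
    h <- G / 2; h2 <- h^2; d <- w - C; den <- h2 + d^2
    J[, j + 1] <- h2 / den
    J[, j + 2] <- A * h * d^2 / den^2
    J[, j + 3] <- 2 * A * h2 * d / den^2
  }
  J
}

#' Fit the five-pool model to one Z-spectrum
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with analytic
#' Jacobian, via \pkg{minpack.lm}) minimizing
#' \eqn{\sum_j (Z(\omega_j) - model(\omega_j))^2}. Non-finite offsets
#' (e.g. dropped during B0 correction) are ignored; the voxel is skipped
#' when fewer than `config$min_offsets` usable points remain. With
#' `multistart > 1`, amplitude initializations are jittered and the best
#' converged solution by deviance is returned.
#'
#' @param spectrum numeric vector of Z values.
#' @param offsets_ppm matching offset axis.
#' @param config a [fit_config()].
#' @param seed seed for the multistart jitter (default from config).
#' @return a `fit_result`: list with `pools` (fitted data frame:
#'   `name`, `center_ppm`, `amplitude`, `fwhm_ppm`), `residual_rms`,
#'   `converged`, `n_offsets_used`, `deviance`, `init_deviance`,
#'   `niter`; or NULL when the voxel is skipped (all-missing spectrum).
#' @export
fit_voxel <- function(spectrum, offsets_ppm, config = fit_config(),
                      seed = config$seed) {
  stopifnot(inherits(config, "fit_config"),
            length(spectrum) == length(offsets_ppm))
  ok <- is.finite(spectrum) & is.finite(offsets_ppm)
  if (!any(ok)) return(NULL)
  if (sum(ok) < config$min_offsets)
    stop(sprintf("only %d usable offsets; need at least %d",
                 sum(ok), config$min_offsets))
  w <- offsets_ppm[ok]
  z <- spectrum[ok]
  pv <- fit_par_vectors(config)
  res_fn <- function(par, w, obs) obs - zmodel_par(par, w)
  jac_fn <- function(par, w, obs) zmodel_jac(par, w)
  starts <- list(pv$init)
  if (config$multistart > 1L) {
    set.seed(seed)
    for (k in seq_len(config$multistart - 1L)) {
      s <- pv$init
      ai <- seq(1, length(s), by = 3)
      s[ai] <- pmin(pmax(s[ai] * stats::runif(length(ai), 0.5, 1.5),
                         pv$lo[ai]), pv$hi[ai])
      starts[[k + 1L]] <- s
    }
  }
  best <- NULL
  init_dev <- sum(res_fn(pv$init, w, z)^2)
  for (s in starts) {
    # convergence is judged from the info code; nls.lm's own warning on
    # hitting maxiter would otherwise flood voxel loops
    fit <- suppressWarnings(minpack.lm::nls.lm(
      par = s, lower = pv$lo, upper = pv$hi, fn = res_fn, jac = jac_fn,
      w = w, obs = z,
      control = minpack.lm::nls.lm.control(
        maxiter = config$max_iterations, ftol = config$ftol,
        ptol = config$ptol)))
    conv <- fit$info %in% 1:4
    cand <- list(fit = fit, conv = conv)
    if (is.null(best) ||
        (fit$deviance < best$fit$deviance - 1e-300) ||
        (fit$deviance == best$fit$deviance && fit$niter < best$fit$niter))
      best <- cand
  }
  par <- best$fit$par
  n <- nrow(config$pools)
  pools <- data.frame(
    name = config$pools$name,
    center_ppm = par[seq(3, 3 * n, by = 3)],
    amplitude = par[seq(1, 3 * n, by = 3)],
    fwhm_ppm = par[seq(2, 3 * n, by = 3)],
    stringsAsFactors = FALSE
  )
  structure(list(pools = pools,
                 residual_rms = sqrt(best$fit$deviance / length(z)),
                 converged = best$conv,
                 n_offsets_used = length(z),
                 deviance = best$fit$deviance,
                 init_deviance = init_dev,
                 niter = best$fit$niter),
            class = "fit_result")
}

#' Area under one fitted Lorentzian pool
#'
#' The per-pool "CEST value": the area under the pool's Lorentzian.
#' The full-line convention integrates over the whole real line,
#' \eqn{AUC = A \Gamma \pi / 2}; the windowed convention integrates over
#' `[a, b]`,
#' \eqn{A (\Gamma/2) [\arctan((b-\delta)/(\Gamma/2)) -
#' \arctan((a-\delta)/(\Gamma/2))]}. AUC is exactly linear in the
#' amplitude under both conventions, so group contrasts do not depend on
#' the choice; absolute values do.
#'
#' @param pool one-row pool data frame or list with `amplitude`,
#'   `fwhm_ppm`, `center_ppm`.
#' @param convention `"analytic_full_line"` (default) or
#'   `"numeric_window"`.
#' @param window_ppm numeric `c(a, b)` for the windowed convention.
#' @return AUC scalar (ppm x normalized-signal units).
#' @export
pool_auc <- function(pool, convention = c("analytic_full_line", "numeric_window"),
                     window_ppm = NULL) {
  convention <- match.arg(convention)
  A <- pool$amplitude; G <- pool$fwhm_ppm; d0 <- pool$center_ppm
  if (!is.finite(G) || G <= 0) stop("pool fwhm_ppm must be positive")
  if (convention == "analytic_full_line") return(A * G * pi / 2)
  if (is.null(window_ppm) || length(window_ppm) != 2L)
    stop("numeric_window needs window_ppm = c(a, b)")
  a <- min(window_ppm); b <- max(window_ppm)
  if (d0 < a || d0 > b)
    warning(sprintf("window [%g, %g] does not contain the pool center %g",
                    a, b, d0))
  h <- G / 2
  A * h * (atan((b - d0) / h) - atan((a - d0) / h))
}

#' Fit every masked voxel of a stack and map per-pool AUC contrasts
#'
#' For each masked voxel: re-align the spectrum with the voxel's B0
#' shift ([correct_spectrum()]), then fit the five-pool model
#' ([fit_voxel()]). Voxels whose field-map quality is `failed` (or NA)
#' are skipped. Emits per-pool amplitude/width/center maps, per-pool AUC
#' maps, a residual map and a convergence map; non-converged or skipped
#' voxels carry NaN in every output. Warns prominently when more than
#' 20% of masked voxels fail to converge.
#'
#' @param stack a normalized [zspec_stack()].
#' @param field_map a `field_map` from [build_field_map()], or NULL to
#'   skip B0 correction.
#' @param config a [fit_config()].
#' @param auc_convention,window_ppm passed to [pool_auc()].
#' @return a `contrast_maps` list: `amplitude`, `fwhm`, `center`, `auc`
#'   (each a named list of matrices, one per pool), `residual_rms`,
#'   `converged` (logical matrix), `pct_nonconverged`, `config_hash`.
#' @export
fit_stack <- function(stack, field_map = NULL, config = fit_config(),
                      auc_convention = "analytic_full_line",
                      window_ppm = NULL) {
  stopifnot(inherits(stack, "zspec_stack"))
  if (!stack$normalized)
    stop("stack must be normalized first (see normalize_stack)")
  if (!is.null(field_map) &&
      !all(dim(field_map$shift_ppm) == dim(stack$mask)))
    stop("field map grid does not match the stack")
  nx <- dim(stack$signal)[1]; ny <- dim(stack$signal)[2]
  pools <- config$pools$name
  blank <- matrix(NA_real_, nx, ny)
  maps <- list(
    amplitude = stats::setNames(rep(list(blank), length(pools)), pools),
    fwhm = stats::setNames(rep(list(blank), length(pools)), pools),
    center = stats::setNames(rep(list(blank), length(pools)), pools),
    auc = stats::setNames(rep(list(blank), length(pools)), pools),
    residual_rms = blank,
    converged = matrix(FALSE, nx, ny)
  )
  idx <- which(stack$mask)
  nvol <- dim(stack$signal)[3]
  flat <- matrix(aperm(stack$signal, c(3, 1, 2)), nrow = nvol)
  n_fit <- 0L; n_conv <- 0L
  for (v in idx) {
    spec <- flat[, v]
    if (!is.null(field_map)) {
      q <- field_map$quality[v]
      if (is.na(q) || q == "failed") next
      spec <- correct_spectrum(spec, stack$offsets_ppm,
                               field_map$shift_ppm[v])
    }
    if (sum(is.finite(spec)) < config$min_offsets) next
    fr <- fit_voxel(spec, stack$offsets_ppm, config)
    if (is.null(fr)) next
    n_fit <- n_fit + 1L
    if (!fr$converged) next
    n_conv <- n_conv + 1L
    maps$converged[v] <- TRUE
    maps$residual_rms[v] <- fr$residual_rms
    for (i in seq_along(pools)) {
      maps$amplitude[[i]][v] <- fr$pools$amplitude[i]
      maps$fwhm[[i]][v] <- fr$pools$fwhm_ppm[i]
      maps$center[[i]][v] <- fr$pools$center_ppm[i]
      maps$auc[[i]][v] <- pool_auc(fr$pools[i, ], auc_convention, window_ppm)
    }
  }
  maps$pct_nonconverged <- if (length(idx))
    100 * (length(idx) - n_conv) / length(idx) else 0
  if (maps$pct_nonconverged > 20)
    warning(sprintf(paste0(
      "%.1f%% of masked voxels did not converge (%d/%d fitted, %d converged); ",
      "inspect the residual map and fit bounds"),
      maps$pct_nonconverged, n_fit, length(idx), n_conv))
  maps$config_hash <- config_hash(config)
  class(maps) <- "contrast_maps"
  maps
}

config_hash <- function(x) {
  s <- utils::capture.output(utils::str(x, digits.d = 15))
  sprintf("%08x", sum(utf8ToInt(paste(s, collapse = "")) *
                        (seq_len(nchar(paste(s, collapse = ""))) %% 251 + 1)) %%
            .Machine$integer.max)
}
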