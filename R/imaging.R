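#' Assemble per-position depth profiles into a scan volume
#'
#' Stacks depth profiles from a lateral scan into one 3D image object on a
#' common depth grid, with the per-voxel validity mask and the surface map
#' carried alongside. Input order does not matter; positions are taken from
#' the `ix`, `iy` columns.
#'
#' @param profiles Tibble with columns `ix`, `iy` and `profile` (list-column
#'   of `depth_profile` tibbles on a common depth grid).
#' @param surfaces Optional tibble `ix`, `iy`, `z_p`, `found` (one row per
#'   position).
#' @param provenance Optional list stored verbatim (configs, seeds, wavelet
#'   spec) -- everything needed to regenerate synthetic inputs bit-exactly.
#' @return A `scan_volume`: list with `voxels` (long tibble `ix`, `iy`, `z`,
#'   `f_B`, `delta_f`, `amplitude`, `valid`), `surface`, `depth`, `nx`,
#'   `ny`, `provenance`.
#' @export
assemble_volume <- function(profiles, surfaces = NULL, provenance = NULL) {
  if (!all(c("ix", "iy", "profile") %in% names(profiles))) {
    stop_invalid("`profiles` must have columns ix, iy, profile.")
  }
  profiles <- dplyr::arrange(profiles, .data$iy, .data$ix)
  z0 <- profiles$profile[[1]]$z
  for (p in profiles$profile) {
    if (length(p$z) != length(z0) || max(abs(p$z - z0)) > 1e-12) {
      stop_invalid("Profiles are on inconsistent depth grids.")
    }
  }
  voxels <- tidyr::unnest(profiles, "profile")
  if (!is.null(surfaces)) {
    surfaces <- dplyr::arrange(surfaces, .data$iy, .data$ix)
  }
  structure(
    list(
      voxels = voxels,
      surface = surfaces,
      depth = z0,
      nx = length(unique(profiles$ix)),
      ny = length(unique(profiles$iy)),
      provenance = provenance
    ),
    class = "scan_volume"
  )
}

#' @export
print.scan_volume <- function(x, ...) {
  cat(sprintf(
    "<scan_volume> %d x %d lateral x %d depth samples\n",
    x$nx, x$ny, length(x$depth)
  ))
  invisible(x)
}

#' Analyse a full simulated or loaded scan
#'
#' Runs the depth-resolved pipeline ([analyze_trace()]) and surface
#' detection ([profile_surface()]) at every lateral position and assembles
#' the results into a [assemble_volume()] scan volume.
#'
#' @param scan A `tof_scan` from [simulate_scan()], or a tibble with
#'   columns `ix`, `iy`, `trace`.
#' @param spec A [wavelet_spec()].
#' @param reference Optional reference from [build_reference()].
#' @param control Control [acoustic_medium()].
#' @param detrend A [detrend_spec()].
#' @param max_depth Analysis depth cap in m.
#' @param probe_wavelength Probe vacuum wavelength in m.
#' @return A `scan_volume`.
#' @export
analyze_scan <- function(scan, spec = wavelet_spec(),
                         reference = NULL,
                         control = if (inherits(scan, "tof_scan")) scan$phantom$control else preset_medium("water"),
                         detrend = detrend_spec(),
                         max_depth = 6e-6,
                         probe_wavelength = 830e-9) {
  traces <- if (inherits(scan, "tof_scan")) scan$traces else scan
  profiles <- dplyr::mutate(
    traces,
    profile = purrr::map(.data$trace, function(tr) {
      analyze_trace(tr, spec, reference, control, detrend, max_depth,
                    probe_wavelength)
    }),
    surface = purrr::map(.data$trace, function(tr) {
      profile_surface(tr, spec, control, control$attenuation, detrend,
                      max_depth, probe_wavelength)
    })
  )
  surfaces <- tidyr::unnest(profiles[c("ix", "iy", "surface")], "surface")
  provenance <- list(
    wavelet = spec,
    config = if (inherits(scan, "tof_scan")) scan$config else NULL,
    control = control,
    max_depth = max_depth,
    probe_wavelength = probe_wavelength
  )
  assemble_volume(profiles[c("ix", "iy", "profile")], surfaces, provenance)
}

#' Segment relative shifts into linearly spaced frequency bins
#'
#' Voxels are labelled by the half-open bin \eqn{[e_i, e_{i+1})} containing
#' their relative shift; the top edge is closed so the maximum of the range
#' falls in the last bin. Labels run from 0 to `n_bins - 1`; values outside
#' the range, and invalid voxels, are `NA`.
#'
#' @param x A `scan_volume`, or a numeric vector of relative shifts (Hz).
#' @param n_bins Number of bins (>= 2).
#' @param range Two-element frequency range in Hz; defaults to the finite
#'   data range.
#' @return For a vector: an integer vector of labels with attribute
#'   `bin_edges`. For a volume: the voxel tibble with a `bin` column added
#'   (class `segmented_map`, attribute `bin_edges`).
#' @export
segment_bins <- function(x, n_bins = 4, range = NULL) {
  UseMethod("segment_bins")
}

#' @export
segment_bins.default <- function(x, n_bins = 4, range = NULL) {
  check_number(n_bins, "n_bins", lower = 2)
  if (is.null(range)) range <- base::range(x, na.rm = TRUE, finite = TRUE)
  if (diff(range) <= 0) stop_invalid("`range` must have positive width.")
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  lab <- findInterval(x, edges, rightmost.closed = TRUE) - 1L
  lab[lab < 0 | lab > n_bins - 1] <- NA_integer_
  structure(as.integer(lab), bin_edges = edges)
}

#' @export
segment_bins.scan_volume <- function(x, n_bins = 4, range = NULL) {
  lab <- segment_bins(x$voxels$delta_f, n_bins, range)
  out <- dplyr::mutate(x$voxels, bin = as.integer(lab))
  class(out) <- c("segmented_map", class(out))
  attr(out, "bin_edges") <- attr(lab, "bin_edges")
  out
}

#' Fit Gaussian layers to a relative-shift depth profile
#'
#' Least-squares fit of `expected_peaks` Gaussians (centre, width,
#' amplitude each) on a zero baseline to \eqn{\Delta f_B(z)}; layer
#' thickness is reported as the fitted FWHM (\eqn{2\sqrt{2\ln 2}\,\sigma}).
#' Peaks are initialised from local maxima ranked by height; if fewer
#' maxima are detectable than requested, the available ones are fitted with
#' a warning.
#'
#' @param profile A `depth_profile` (or any tibble with `z` and `delta_f`).
#' @param expected_peaks Number of Gaussian layers to fit (>= 1).
#' @param fit_range Optional depth window `c(zmin, zmax)` in m.
#' @param init_width Initial Gaussian sigma in m (default 150 nm).
#' @return A `layer_fit` tibble, one row per fitted peak: `peak`, `centre`,
#'   `sigma`, `fwhm`, `amplitude`, with attributes `residual` (RSS),
#'   `converged`, and `fitted` (predicted curve). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_layers <- function(profile, expected_peaks, fit_range = NULL,
                       init_width = 150e-9) {
  check_number(expected_peaks, "expected_peaks", lower = 1)
  dat <- tibble(z = profile$z, y = profile$delta_f)
  if ("valid" %in% names(profile)) dat <- dat[profile$valid, ]
  dat <- dat[is.finite(dat$y), ]
  if (!is.null(fit_range)) {
    dat <- dat[dat$z >= fit_range[1] & dat$z <= fit_range[2], ]
  }
  if (nrow(dat) < 3 * expected_peaks + 1) {
    stop_invalid("Too few samples for the requested number of peaks.")
  }
  pk <- pracma::findpeaks(dat$y, npeaks = as.integer(expected_peaks),
                          sortstr = TRUE)
  if (is.null(pk)) {
    # no interior maxima: fall back to the global maximum
    i <- which.max(dat$y)
    pk <- matrix(c(dat$y[i], i, NA, NA), nrow = 1)
  }
  n_found <- nrow(pk)
  if (n_found < expected_peaks) {
    warn(sprintf("Only %d of %d requested peaks detectable; fitting those.",
                 n_found, expected_peaks))
  }
  k <- n_found
  p0 <- c(rbind(pk[, 1], dat$z[pk[, 2]], rep(init_width, k)))
  model <- function(p, z) {
    y <- 0
    for (j in seq_len(k)) {
      A <- p[3 * j - 2]; mu <- p[3 * j - 1]; s <- p[3 * j]
      y <- y + A * exp(-(z - mu)^2 / (2 * s^2))
    }
    y
  }
  res_fun <- function(p) dat$y - model(p, dat$z)
  lower <- rep(c(-Inf, min(dat$z), 1e-9), k)
  upper <- rep(c(Inf, max(dat$z), diff(range(dat$z))), k)
  fit <- minpack.lm::nls.lm(
    par = p0, fn = res_fun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- fit$par
  ord <- order(p[seq(2, 3 * k, by = 3)])
  out <- tibble(
    peak = seq_len(k),
    centre = p[seq(2, 3 * k, by = 3)][ord],
    sigma = abs(p[seq(3, 3 * k, by = 3)])[ord],
    amplitude = p[seq(1, 3 * k, by = 3)][ord]
  )
  out$fwhm <- 2 * sqrt(2 * log(2)) * out$sigma
  out <- out[c("peak", "centre", "sigma", "fwhm", "amplitude")]
  class(out) <- c("layer_fit", class(out))
  attr(out, "residual") <- sum(fit$fvec^2)
  attr(out, "converged") <- fit$info %in% 1:4
  attr(out, "fitted") <- tibble(z = dat$z, y = dat$y,
                                fit = model(p, dat$z))
  out
}

# window-coverage kernel matrix for a region partition of the depth axis:
# column r is the Gaussian-envelope coverage of region [a_r, b_r) at each z
coverage_kernels <- function(z, bounds_app, sigma_z) {
  a <- c(0, bounds_app)
  b <- c(bounds_app, Inf)
  vapply(seq_along(a), function(r) {
    pnorm((b[r] - z) / sigma_z) - pnorm((a[r] - z) / sigma_z)
  }, numeric(length(z)))
}

# apparent region boundaries of a stack for candidate layer shifts df_hat
apparent_bounds <- function(stack, control, df_hat, probe_wavelength) {
  f0 <- brillouin_frequency(control, probe_wavelength)
  n_l <- purrr::map_dbl(stack$layers, ~ .x$medium$refractive_index)
  thick <- purrr::map_dbl(stack$layers, "thickness")
  v_l <- sound_velocity_from_shift(f0 + df_hat, n_l, probe_wavelength)
  v_med <- control$sound_velocity
  cumsum(c(stack$standoff, thick * v_med / v_l))
}

#' Window-response-aware layer plateau estimation
#'
#' The wavelet ridge through a stack of layers thinner than the analysis
#' window is a smoothed version of the true piecewise-constant profile, so
#' reading plateau values straight off the ridge underestimates thin-layer
#' contrast. This estimator inverts the smoothing: the ridge is modelled as
#' a linear mixture of per-region window-coverage kernels (Gaussian
#' envelope, sigma from the window FWHM) and the per-layer shifts are
#' recovered by amplitude-squared-weighted least squares. Region boundaries
#' depend on the layer velocities, so the geometry is refined once from the
#' first-pass estimates. Optionally, residual estimator bias is removed by a
#' parametric bootstrap: synthetic traces are regenerated at the estimate
#' and the estimator's own offset on them is subtracted.
#'
#' @param profile A `depth_profile` from [analyze_trace()] (with
#'   `amplitude`).
#' @param stack The [layer_stack()] geometry (thicknesses and stand-off are
#'   used; layer velocities are re-derived from the estimates).
#' @param control Control [acoustic_medium()].
#' @param spec The [wavelet_spec()] used to produce `profile`.
#' @param reference The reference used to produce `profile` (or `NULL` for
#'   the flat theoretical reference).
#' @param cfg The [simulation_config()] for bootstrap regeneration;
#'   required when `nboot > 0`.
#' @param fit_range Depth window in m over which the mixture is fitted.
#' @param nboot Bootstrap replicates for bias correction (0 disables).
#' @param boot_seed Seed for the bootstrap noise draws; defaults to a
#'   sub-stream of `cfg$seed`.
#' @param probe_wavelength Probe vacuum wavelength in m.
#' @param detrend,max_depth Passed to the re-analysis of bootstrap traces.
#' @return A tibble with one row per layer: `layer`, `delta_f` (Hz,
#'   bias-corrected when `nboot > 0`), `delta_f_raw`.
#' @export
layer_plateaus <- function(profile, stack, control, spec,
                           reference = NULL, cfg = NULL,
                           fit_range = c(0.5e-6, 5.5e-6),
                           nboot = 6, boot_seed = NULL,
                           probe_wavelength = 830e-9,
                           detrend = detrend_spec(), max_depth = 6e-6) {
  n_layers <- length(stack$layers)
  if (n_layers == 0) stop_invalid("`stack` has no layers to quantify.")
  sigma_z <- spec$window_fwhm_z / (2 * sqrt(2 * log(2)))

  estimate <- function(prof) {
    sel <- prof$valid & is.finite(prof$delta_f) &
      prof$z >= fit_range[1] & prof$z <= fit_range[2]
    z <- prof$z[sel]
    y <- prof$delta_f[sel]
    w <- prof$amplitude[sel]^2
    fit_once <- function(df_geom) {
      K <- coverage_kernels(z, apparent_bounds(stack, control, df_geom,
                                               probe_wavelength), sigma_z)
      stats::lm.wfit(K, y, w)$coefficients
    }
    c0 <- fit_once(rep(0, n_layers))[1 + seq_len(n_layers)]
    fit_once(c0)[1 + seq_len(n_layers)] # refined geometry
  }

  est <- estimate(profile)
  raw <- est
  if (nboot > 0) {
    if (is.null(cfg)) {
      stop_invalid("`cfg` is required for bootstrap bias correction.")
    }
    if (is.null(boot_seed)) {
      boot_seed <- if (!is.null(cfg$seed)) (cfg$seed %% 2000000000L) + 7L else NULL
    }
    f0 <- brillouin_frequency(control, probe_wavelength)
    layers_hat <- purrr::map2(stack$layers, est, function(ly, df) {
      m <- ly$medium
      list(
        medium = acoustic_medium(
          m$name, m$refractive_index, m$mass_density,
          sound_velocity_from_shift(f0 + df, m$refractive_index,
                                    probe_wavelength),
          m$attenuation, m$scatter_strength
        ),
        thickness = ly$thickness
      )
    })
    stack_hat <- layer_stack(stack$standoff, layers_hat, stack$backing)
    seeds <- child_seeds(boot_seed, nboot)
    boots <- vapply(seeds, function(s) {
      cfg_b <- cfg
      cfg_b$seed <- if (is.na(s)) NULL else s
      tr <- simulate_trace(stack_hat, control, cfg_b)
      prof_b <- analyze_trace(tr, spec, reference, control, detrend,
                              max_depth, probe_wavelength)
      estimate(prof_b)
    }, numeric(n_layers))
    boots <- matrix(boots, nrow = n_layers)
    est <- est + (est - rowMeans(boots))
  }
  tibble(
    layer = purrr::map_chr(stack$layers, ~ .x$medium$name),
    delta_f = unname(est),
    delta_f_raw = unname(raw)
  )
}

#' Approach-curve analysis of a stand-off series
#'
#' For each step of an approach series, computes the amplitude-weighted
#' average Brillouin shift of the whole trace and the depth-resolved ridge.
#' As the stand-off shrinks and the specimen enters the depth measurement
#' range, the weighted average departs from the control baseline -- the
#' activation signal used to choose a stand-off before scanning.
#'
#' @param series An `approach_series` from [simulate_approach_series()].
#' @param spec A [wavelet_spec()].
#' @param reference,control,detrend,max_depth,probe_wavelength As in
#'   [analyze_trace()].
#' @return A tibble with columns `standoff`, `weighted_shift` (Hz) and
#'   `profile` (list-column of `depth_profile`).
#' @export
approach_curve <- function(series, spec = wavelet_spec(),
                           reference = NULL,
                           control = preset_medium("water"),
                           detrend = detrend_spec(),
                           max_depth = 6e-6,
                           probe_wavelength = 830e-9) {
  out <- dplyr::mutate(
    tibble(standoff = series$standoff),
    analysis = purrr::map(series$trace, function(tr) {
      det <- remove_background(tr, detrend)
      spg <- cwt_spectrogram(det, spec, max_depth)
      prof <- analyze_trace(tr, spec, reference, control, detrend,
                            max_depth, probe_wavelength)
      list(shift = weighted_average_shift(spg), profile = prof)
    })
  )
  dplyr::transmute(
    out,
    standoff = .data$standoff,
    weighted_shift = purrr::map_dbl(.data$analysis, "shift"),
    profile = purrr::map(.data$analysis, "profile")
  )
}
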