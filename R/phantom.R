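#' Layered specimen description for the simulator
#'
#' A layer stack describes everything the acoustic wavefront traverses after
#' leaving the fibre tip: a control-medium gap (`standoff`) between the
#' transducer face and the specimen surface, an ordered list of finite
#' layers, and a semi-infinite backing medium. Acoustic transmission across
#' interfaces is treated as total -- no partial reflections or impedance
#' mismatch echoes; per-medium `scatter_strength` models photoelastic
#' amplitude differences instead.
#'
#' @param standoff Control-medium gap in m, non-negative.
#' @param layers List of layers, each a list with elements `medium` (an
#'   [acoustic_medium()]) and `thickness` (m, positive). May be empty.
#' @param backing Semi-infinite [acoustic_medium()] behind the last layer.
#' @return An object of class `layer_stack`.
#' @export
layer_stack <- function(standoff, layers = list(), backing) {
  check_number(standoff, "standoff", lower = 0)
  if (!inherits(backing, "acoustic_medium")) {
    stop_invalid("`backing` must be an acoustic_medium.")
  }
  for (ly in layers) {
    if (!inherits(ly$medium, "acoustic_medium")) {
      stop_invalid("Each layer must carry an acoustic_medium as `medium`.")
    }
    check_number(ly$thickness, "thickness", lower = 0, strict = TRUE)
  }
  structure(
    list(standoff = standoff, layers = layers, backing = backing),
    class = "layer_stack"
  )
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf(
    "<layer_stack> standoff %.3g um, %d layer(s), backing '%s'\n",
    x$standoff * 1e6, length(x$layers), x$backing$name
  ))
  for (ly in x$layers) {
    cat(sprintf("  %-12s %7.0f nm  (v = %.1f m/s)\n",
                ly$medium$name, ly$thickness * 1e9, ly$medium$sound_velocity))
  }
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of one synthetic acquisition. The simulated reflectivity signal
#' is the sum of (1) a coincidence peak at t = 0 -- a narrow Gaussian of
#' configurable width standing in for the electronic-coincidence transient,
#' (2) a slow single-exponential thermal background, (3) the Brillouin
#' time-of-flight oscillation, and (4) additive white Gaussian noise.
#'
#' `n_average` emulates on-instrument signal averaging: the stored trace is
#' the mean of that many repeated acquisitions, so the effective noise
#' standard deviation is `noise_sigma / sqrt(n_average)`.
#'
#' @param optics An [optical_config()].
#' @param coincidence_amplitude Amplitude of the coincidence peak (reflectivity
#'   units relative to a unit Brillouin oscillation).
#' @param coincidence_width FWHM of the coincidence Gaussian in s.
#' @param thermal_amplitude Initial amplitude of the thermal background.
#' @param thermal_decay Exponential decay time of the thermal background in s.
#' @param noise_sigma Standard deviation of the additive Gaussian noise per
#'   sample per acquisition, non-negative.
#' @param n_average Number of averaged repeat acquisitions (integer >= 1).
#' @param seed Integer seed; a fixed seed makes output bit-identical.
#'   `NULL` leaves the RNG state alone.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(optics = optical_config(),
                              coincidence_amplitude = 20,
                              coincidence_width = 10e-12,
                              thermal_amplitude = 5,
                              thermal_decay = 5e-9,
                              noise_sigma = 0.1,
                              n_average = 1,
                              seed = NULL) {
  if (!inherits(optics, "optical_config")) {
    stop_invalid("`optics` must be an optical_config.")
  }
  check_number(noise_sigma, "noise_sigma", lower = 0)
  check_number(thermal_decay, "thermal_decay", lower = 0, strict = TRUE)
  check_number(n_average, "n_average", lower = 1)
  structure(
    list(
      optics = optics,
      coincidence_amplitude = coincidence_amplitude,
      coincidence_width = coincidence_width,
      thermal_amplitude = thermal_amplitude,
      thermal_decay = thermal_decay,
      noise_sigma = noise_sigma,
      n_average = as.integer(n_average),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# flatten a stack into ordered regions: control gap, layers, backing.
# boundaries are exact; time boundaries are when the wavefront crosses them.
stack_regions <- function(stack, control) {
  media <- c(
    list(control),
    purrr::map(stack$layers, "medium"),
    list(stack$backing)
  )
  thickness <- c(
    stack$standoff,
    purrr::map_dbl(stack$layers, "thickness"),
    Inf
  )
  # a zero standoff collapses the control region
  keep <- thickness > 0
  media <- media[keep]
  thickness <- thickness[keep]
  tibble(
    name = purrr::map_chr(media, "name"),
    refractive_index = purrr::map_dbl(media, "refractive_index"),
    mass_density = purrr::map_dbl(media, "mass_density"),
    sound_velocity = purrr::map_dbl(media, "sound_velocity"),
    attenuation = purrr::map_dbl(media, "attenuation"),
    scatter_strength = purrr::map_dbl(media, "scatter_strength"),
    thickness = thickness,
    z_start = cumsum(c(0, thickness[-length(thickness)])),
    z_end = cumsum(thickness)
  )
}

new_tof_trace <- function(time, amplitude, config, position, truth) {
  out <- tibble(time = time, amplitude = amplitude)
  class(out) <- c("tof_trace", class(out))
  attr(out, "config") <- config
  attr(out, "position") <- position
  attr(out, "truth") <- truth
  out
}

#' Simulate one time-resolved Brillouin scattering trace
#'
#' Propagates a single coherent acoustic wavefront through the stack at the
#' local sound velocity and accumulates the Brillouin interference phase
#' \eqn{\phi(t) = \int_0^t 2\pi f_B(z(t')) dt'} with \eqn{f_B} from the local
#' medium at the wavefront (the phase is continuous across layer
#' boundaries). The Brillouin component is
#' \eqn{B(t) = s(z) \exp(-\int_0^z \alpha dz') \cos\phi(t)}, to which the
#' coincidence peak, thermal background, and seeded Gaussian noise are added.
#' Integrals are evaluated exactly (piecewise linear in each region).
#'
#' @param stack A [layer_stack()].
#' @param control Control [acoustic_medium()] filling the standoff gap.
#' @param cfg A [simulation_config()].
#' @param position Optional `c(x, y)` lateral grid indices stored as metadata.
#' @return A `tof_trace`: a tibble with columns `time` (s, uniform grid
#'   starting at 0) and `amplitude`, carrying attributes `config`, `position`
#'   and `truth`. The ground truth lists the traversed regions with their
#'   Brillouin frequencies, the true and control-velocity-apparent boundary
#'   depths, and the specimen surface position.
#' @examples
#' w <- preset_medium("water")
#' tr <- simulate_trace(
#'   layer_stack(0, list(), w), w,
#'   simulation_config(noise_sigma = 0, seed = 1)
#' )
#' @export
simulate_trace <- function(stack, control, cfg, position = NULL) {
  if (!inherits(stack, "layer_stack")) stop_invalid("`stack` must be a layer_stack.")
  if (!inherits(control, "acoustic_medium")) {
    stop_invalid("`control` must be an acoustic_medium.")
  }
  if (!inherits(cfg, "simulation_config")) {
    stop_invalid("`cfg` must be a simulation_config.")
  }
  opt <- cfg$optics
  dt <- opt$sampling_period
  tt <- seq(0, opt$sweep_span, by = dt)
  n <- length(tt)

  reg <- stack_regions(stack, control)
  fB <- brillouin_frequency(reg, opt$probe_wavelength)
  t_cross <- cumsum(reg$thickness / reg$sound_velocity) # wavefront at z_end
  t_enter <- c(0, t_cross[-length(t_cross)])

  # piecewise-exact cumulative phase, depth and attenuation at region entries
  seg_t <- pmin(t_cross, max(tt)) - pmin(t_enter, max(tt))
  phi0 <- cumsum(c(0, (2 * pi * fB * seg_t)[-length(seg_t)]))
  att0 <- cumsum(c(0, (reg$attenuation * reg$sound_velocity * seg_t)[-length(seg_t)]))

  idx <- findInterval(tt, t_enter) # region index per sample
  dt_in <- tt - t_enter[idx]
  phi <- phi0[idx] + 2 * pi * fB[idx] * dt_in
  att <- att0[idx] + reg$attenuation[idx] * reg$sound_velocity[idx] * dt_in
  brillouin <- reg$scatter_strength[idx] * exp(-att) * cos(phi)

  coincidence <- cfg$coincidence_amplitude *
    exp(-4 * log(2) * (tt / cfg$coincidence_width)^2)
  thermal <- cfg$thermal_amplitude * exp(-tt / cfg$thermal_decay)

  amplitude <- coincidence + thermal + brillouin
  if (cfg$noise_sigma > 0) {
    sigma_eff <- cfg$noise_sigma / sqrt(cfg$n_average)
    noise <- with_seed(cfg$seed, stats::rnorm(n, 0, sigma_eff))
    amplitude <- amplitude + noise
  }

  v_med <- control$sound_velocity
  truth <- list(
    regions = dplyr::mutate(
      reg,
      f_B = fB,
      t_enter = t_enter,
      t_exit = t_cross,
      z_start_apparent = v_med * t_enter,
      z_end_apparent = v_med * t_cross
    ),
    surface_z = stack$standoff,
    surface_z_apparent = stack$standoff, # gap is control medium: identical
    control = control
  )
  new_tof_trace(tt, amplitude, cfg, position, truth)
}

#' Ground-truth Brillouin frequency at depth
#'
#' Evaluates the simulated specimen's true Brillouin frequency profile at
#' requested depths, using either true depth or the control-velocity
#' apparent depth convention (`z = v_med t`).
#'
#' @param trace A `tof_trace` from [simulate_trace()].
#' @param z Depths in m.
#' @param apparent Use the apparent-depth convention (default `TRUE`, the
#'   convention of the analysis pipeline).
#' @return Brillouin frequencies in Hz.
#' @export
truth_frequency <- function(trace, z, apparent = TRUE) {
  truth <- attr(trace, "truth")
  if (is.null(truth)) stop_invalid("`trace` carries no ground truth.")
  reg <- truth$regions
  starts <- if (apparent) reg$z_start_apparent else reg$z_start
  reg$f_B[pmax(1L, findInterval(z, starts))]
}

#' Lateral scan phantom
#'
#' A lateral grid of layer stacks sharing one control medium; the simulator
#' turns it into one trace per grid point.
#'
#' @param nx,ny Grid dimensions (positive integers).
#' @param pitch Lateral pitch in m.
#' @param stack_fun Function `(ix, iy) -> layer_stack` defining the stack at
#'   each grid point (1-based indices).
#' @param control Shared control [acoustic_medium()].
#' @return An object of class `scan_phantom`.
#' @export
scan_phantom <- function(nx, ny, pitch, stack_fun, control) {
  check_number(nx, "nx", lower = 1)
  check_number(ny, "ny", lower = 1)
  check_number(pitch, "pitch", lower = 0, strict = TRUE)
  grid <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny))
  stacks <- purrr::map2(grid$ix, grid$iy, stack_fun)
  structure(
    list(
      nx = as.integer(nx), ny = as.integer(ny), pitch = pitch,
      grid = dplyr::mutate(grid, stack = stacks),
      control = control
    ),
    class = "scan_phantom"
  )
}

#' Nematode cuticle layer phantom
#'
#' Builds the layered cuticle stack: cortical, liquid-filled medial, basal,
#' then lipid-rich hypodermis, immersed in a control medium. Layer sound
#' velocities are derived by inverting the Brillouin relation at the tissue
#' refractive index around the control-medium baseline frequency, so each
#' layer produces the configured relative shift \eqn{\Delta f_B}. The strut
#' variant replaces the medial layer with a stiff collagen-column material.
#'
#' Default shifts are +300 MHz (cortical), +60 MHz (medial), +300 MHz
#' (basal), -200 MHz (hypodermis) and +600 MHz for the strut; default
#' thicknesses 320 nm, 400 nm, 320 nm and 1.5 um. The backing is
#' zero-shift tissue (body interior).
#'
#' @param delta_f Named numeric: relative shifts in Hz for `cortical`,
#'   `medial`, `basal`, `hypodermis`.
#' @param thickness Layer thicknesses in m, same order, positive.
#' @param standoff Control gap between fibre tip and cuticle surface in m.
#' @param strut Replace the medial layer by strut material (`TRUE`/`FALSE`).
#' @param strut_delta_f Strut relative shift in Hz.
#' @param control Control [acoustic_medium()].
#' @param probe_wavelength Probe vacuum wavelength in m.
#' @param tissue_index,tissue_density Refractive index and density (kg/m^3)
#'   shared by all cuticle layers.
#' @param tissue_attenuation Phonon attenuation in the layers, 1/m.
#' @return A [layer_stack()].
#' @export
build_cuticle_phantom <- function(delta_f = c(cortical = 300e6, medial = 60e6,
                                              basal = 300e6, hypodermis = -200e6),
                                  thickness = c(320e-9, 400e-9, 320e-9, 1.5e-6),
                                  standoff = 1.5e-6,
                                  strut = FALSE,
                                  strut_delta_f = 600e6,
                                  control = preset_medium("water"),
                                  probe_wavelength = 830e-9,
                                  tissue_index = 1.38,
                                  tissue_density = 1200,
                                  tissue_attenuation = control$attenuation) {
  if (length(delta_f) != 4 || length(thickness) != 4) {
    stop_invalid("`delta_f` and `thickness` must each have 4 entries.")
  }
  check_number(thickness, "thickness", lower = 0, strict = TRUE)
  f0 <- brillouin_frequency(control, probe_wavelength)
  names(delta_f) <- c("cortical", "medial", "basal", "hypodermis")
  if (strut) delta_f[["medial"]] <- strut_delta_f
  nm <- names(delta_f)
  if (strut) nm[2] <- "strut"
  mk <- function(name, df) {
    acoustic_medium(
      name, tissue_index, tissue_density,
      sound_velocity_from_shift(f0 + df, tissue_index, probe_wavelength),
      attenuation = tissue_attenuation
    )
  }
  layers <- purrr::map2(nm, unname(delta_f), function(name, df) {
    list(medium = mk(name, df), thickness = NA_real_)
  })
  for (i in seq_along(layers)) layers[[i]]$thickness <- thickness[i]
  layer_stack(standoff, layers, backing = mk("interior", 0))
}

#' Cell-on-dish dome phantom
#'
#' A lateral scan phantom of a single adherent cell: a smooth paraboloid
#' dome of `cell_medium` sitting on a rigid dish, immersed in control
#' medium. The stand-off at each pixel is the tip-to-dish distance minus the
#' local cell height; outside the cell footprint the column is pure control
#' medium down to the dish.
#'
#' @param height Peak dome height in m (0 gives an all-control phantom).
#' @param cell_medium [acoustic_medium()] of the cell body.
#' @param nx,ny,pitch Lateral grid (pixels and pitch in m).
#' @param tip_height Tip-to-dish distance in m; must exceed `height`.
#' @param footprint_radius Dome footprint radius in m.
#' @param control Control [acoustic_medium()].
#' @param dish Dish [acoustic_medium()] used as backing.
#' @return A [scan_phantom()] whose ground-truth surface map is the dome
#'   profile.
#' @export
build_cell_phantom <- function(height = 3e-6,
                               cell_medium = acoustic_medium(
                                 "cell", 1.38, 1100, 1600, attenuation = 5e5
                               ),
                               nx = 11, ny = 11, pitch = 1e-6,
                               tip_height = 5e-6,
                               footprint_radius = 4e-6,
                               control = preset_medium("water"),
                               dish = acoustic_medium(
                                 "dish", 1.59, 1050, 2350, attenuation = 1e5
                               )) {
  check_number(height, "height", lower = 0)
  if (height >= tip_height) {
    stop_invalid("`height` must be smaller than `tip_height`.")
  }
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  dome <- function(ix, iy) {
    r <- pitch * sqrt((ix - cx)^2 + (iy - cy)^2)
    if (r >= footprint_radius) return(0)
    height * (1 - (r / footprint_radius)^2)
  }
  stack_fun <- function(ix, iy) {
    h <- dome(ix, iy)
    if (h <= 0) {
      layer_stack(tip_height, list(), backing = dish)
    } else {
      layer_stack(
        tip_height - h,
        list(list(medium = cell_medium, thickness = h)),
        backing = dish
      )
    }
  }
  phantom <- scan_phantom(nx, ny, pitch, stack_fun, control)
  phantom$truth_surface <- dplyr::mutate(
    tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny)),
    height = purrr::map2_dbl(.data$ix, .data$iy, dome)
  )
  phantom$tip_height <- tip_height
  phantom
}

#' Simulate a full lateral scan
#'
#' One trace per lateral grid point with independent noise draws from a
#' per-position sub-stream of the configured seed: the same phantom, config
#' and seed always reproduce the scan bit-exactly, and each position's noise
#' is independent of the others.
#'
#' @param phantom A [scan_phantom()].
#' @param cfg A [simulation_config()].
#' @return A `tof_scan`: list with `traces` (tibble of `ix`, `iy` and a
#'   `trace` list-column), `surface` (ground-truth stand-off per position),
#'   `phantom` and `config`.
#' @export
simulate_scan <- function(phantom, cfg) {
  if (!inherits(phantom, "scan_phantom")) {
    stop_invalid("`phantom` must be a scan_phantom.")
  }
  grid <- phantom$grid
  if (nrow(grid) == 0) stop_invalid("Phantom grid is empty.")
  seeds <- child_seeds(cfg$seed, nrow(grid))
  traces <- purrr::pmap(
    list(grid$ix, grid$iy, grid$stack, seeds),
    function(ix, iy, stack, seed) {
      cfg_i <- cfg
      cfg_i$seed <- if (is.na(seed)) NULL else seed
      simulate_trace(stack, phantom$control, cfg_i, position = c(ix, iy))
    }
  )
  structure(
    list(
      traces = dplyr::mutate(grid[c("ix", "iy")], trace = traces),
      surface = dplyr::mutate(
        grid[c("ix", "iy")],
        standoff = purrr::map_dbl(grid$stack, "standoff")
      ),
      phantom = phantom,
      config = cfg
    ),
    class = "tof_scan"
  )
}

#' Simulate an approach series
#'
#' Re-simulates the same stack while stepping the fibre tip towards the
#' specimen (decreasing stand-off), as when selecting a stand-off before a
#' lateral scan.
#'
#' @param stack A [layer_stack()]; its own `standoff` is ignored.
#' @param standoffs Non-negative, non-increasing stand-off values in m.
#' @param cfg A [simulation_config()].
#' @param control Control [acoustic_medium()].
#' @return An `approach_series`: tibble with columns `standoff` and `trace`
#'   (list-column of `tof_trace`).
#' @export
simulate_approach_series <- function(stack, standoffs, cfg,
                                     control = preset_medium("water")) {
  check_number(standoffs, "standoffs", lower = 0)
  if (is.unsorted(rev(standoffs), strictly = FALSE)) {
    stop_invalid("`standoffs` must be non-increasing (approaching the specimen).")
  }
  seeds <- child_seeds(cfg$seed, length(standoffs))
  traces <- purrr::map2(standoffs, seeds, function(s, seed) {
    cfg_i <- cfg
    cfg_i$seed <- if (is.na(seed)) NULL else seed
    simulate_trace(
      layer_stack(s, stack$layers, stack$backing), control, cfg_i
    )
  })
  out <- tibble(standoff = standoffs, trace = traces)
  class(out) <- c("approach_series", class(out))
  out
}
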