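#' Define a homogeneous acoustic medium
#'
#' An acoustic medium bundles the optical and acoustic material constants
#' needed to predict and simulate Brillouin scattering in one homogeneous
#' region: refractive index \eqn{n}, mass density \eqn{\rho} (kg/m^3),
#' longitudinal sound velocity \eqn{v} (m/s), amplitude attenuation of the
#' phonon field \eqn{\alpha} (1/m), and a dimensionless photoelastic scatter
#' strength that scales the Brillouin oscillation amplitude relative to other
#' media in the same specimen.
#'
#' All quantities are SI. Attenuation here is the amplitude (not intensity)
#' decay rate of the propagating acoustic wavefront.
#'
#' @param name Label for the medium.
#' @param refractive_index Refractive index \eqn{n \ge 1} at the probe
#'   wavelength.
#' @param mass_density Mass density \eqn{\rho} in kg/m^3, positive.
#' @param sound_velocity Longitudinal sound velocity \eqn{v} in m/s, positive.
#' @param attenuation Phonon amplitude attenuation \eqn{\alpha} in 1/m,
#'   non-negative.
#' @param scatter_strength Relative photoelastic oscillation amplitude,
#'   non-negative; 1 by convention for the control medium.
#'
#' @return An object of class `acoustic_medium` (a named list).
#' @examples
#' water <- acoustic_medium("water", 1.33, 1000, 1497, attenuation = 5e5)
#' brillouin_frequency(water, 830e-9)
#' @export
acoustic_medium <- function(name, refractive_index, mass_density,
                            sound_velocity, attenuation = 0,
                            scatter_strength = 1) {
  check_number(refractive_index, "refractive_index", lower = 1)
  check_number(mass_density, "mass_density", lower = 0, strict = TRUE)
  check_number(sound_velocity, "sound_velocity", lower = 0)
  check_number(attenuation, "attenuation", lower = 0)
  check_number(scatter_strength, "scatter_strength", lower = 0)
  structure(
    list(
      name = as.character(name),
      refractive_index = refractive_index,
      mass_density = mass_density,
      sound_velocity = sound_velocity,
      attenuation = attenuation,
      scatter_strength = scatter_strength
    ),
    class = "acoustic_medium"
  )
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf(
    "<acoustic_medium> %s: n = %.3f, rho = %g kg/m^3, v = %g m/s, alpha = %g 1/m, scatter = %g\n",
    x$name, x$refractive_index, x$mass_density, x$sound_velocity,
    x$attenuation, x$scatter_strength
  ))
  invisible(x)
}

#' Shipped medium presets
#'
#' Returns the built-in media as a tibble (one row per medium). `"water"`
#' doubles as a phosphate-buffered-saline-like control medium (n = 1.33,
#' v = 1497 m/s at room temperature, a literature-standard value, here
#' configurable rather than measured); `"tissue"` is a generic soft-tissue
#' medium (n = 1.38, rho = 1200 kg/m^3). The water attenuation default,
#' 5e5 1/m, is the classical frequency-squared extrapolation of water's
#' acoustic absorption to ~5 GHz.
#'
#' @return A tibble with columns `name`, `refractive_index`, `mass_density`,
#'   `sound_velocity`, `attenuation`, `scatter_strength`.
#' @seealso [preset_medium()] to materialise one row as an
#'   [acoustic_medium()].
#' @export
medium_presets <- function() {
  tibble(
    name = c("water", "tissue"),
    refractive_index = c(1.33, 1.38),
    mass_density = c(1000, 1200),
    sound_velocity = c(1497, 1540),
    attenuation = c(5e5, 5e5),
    scatter_strength = c(1, 1)
  )
}

#' @rdname medium_presets
#' @param name Preset name, one of `medium_presets()$name`.
#' @export
preset_medium <- function(name) {
  presets <- medium_presets()
  row <- presets[presets$name == name, ]
  if (nrow(row) != 1) {
    stop_invalid(sprintf(
      "Unknown medium preset '%s'; available: %s.",
      name, paste(presets$name, collapse = ", ")
    ))
  }
  acoustic_medium(
    row$name, row$refractive_index, row$mass_density, row$sound_velocity,
    row$attenuation, row$scatter_strength
  )
}

#' Read media definitions from a plain-text config file
#'
#' The file is YAML with one top-level entry per medium; each entry is a
#' key/value mapping with fields `n` (or `refractive_index`), `rho`
#' (`mass_density`), `v` (`sound_velocity`), and optionally `alpha`
#' (`attenuation`, default 0) and `scatter_strength` (default 1).
#'
#' @param path Path to the config file.
#' @return A named list of [acoustic_medium()] objects.
#' @export
read_media <- function(path) {
  # keep a bare `n:` key a key (YAML 1.1 would bool-ify it), and accept
  # plain scientific notation like 2.0e5 that YAML 1.1 leaves as text
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) "n",
    "bool#yes" = function(x) "y"
  ))
  if (length(raw) == 0) stop_invalid("Media config is empty.")
  pick <- function(entry, keys) {
    for (k in keys) {
      v <- entry[[k]]
      if (!is.null(v)) {
        if (is.character(v)) v <- as.numeric(v)
        return(v)
      }
    }
    NULL
  }
  out <- purrr::imap(raw, function(entry, nm) {
    n <- pick(entry, c("n", "refractive_index"))
    rho <- pick(entry, c("rho", "mass_density"))
    v <- pick(entry, c("v", "sound_velocity"))
    if (is.null(n) || is.null(rho) || is.null(v)) {
      stop_invalid(sprintf("Medium '%s' must define n, rho and v.", nm))
    }
    acoustic_medium(
      nm, n, rho, v,
      attenuation = pick(entry, c("alpha", "attenuation")) %||% 0,
      scatter_strength = pick(entry, "scatter_strength") %||% 1
    )
  })
  out
}

#' Optical acquisition configuration
#'
#' Time base and wavelengths of the asynchronous-optical-sampling pump-probe
#' acquisition. Defaults follow a dual Ti:Sapphire system: probe 830 nm, pump
#' 780 nm (metadata only), delay sweep 0--12.5 ns, ~3 ps sampling period.
#'
#' @param probe_wavelength Probe vacuum wavelength in m.
#' @param pump_wavelength Pump vacuum wavelength in m (metadata only).
#' @param sweep_span Pump-probe delay window in s.
#' @param sampling_period Delay sampling period in s.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(probe_wavelength = 830e-9,
                           pump_wavelength = 780e-9,
                           sweep_span = 12.5e-9,
                           sampling_period = 3e-12) {
  check_number(probe_wavelength, "probe_wavelength", lower = 0, strict = TRUE)
  check_number(sampling_period, "sampling_period", lower = 0, strict = TRUE)
  if (sweep_span <= sampling_period) {
    stop_invalid("`sweep_span` must exceed `sampling_period`.")
  }
  structure(
    list(
      probe_wavelength = probe_wavelength,
      pump_wavelength = pump_wavelength,
      sweep_span = sweep_span,
      sampling_period = sampling_period
    ),
    class = "optical_config"
  )
}

as_medium_fields <- function(medium) {
  if (inherits(medium, "acoustic_medium")) return(medium)
  if (is.data.frame(medium)) return(as.list(medium))
  if (is.list(medium)) return(medium)
  stop_invalid("`medium` must be an acoustic_medium, list or data frame.")
}

#' Brillouin frequency shift of a medium
#'
#' At normal probe incidence the backscattered Brillouin frequency is
#' \deqn{f_B = 2 n v / \lambda_{probe},}
#' the rate at which the interference phase between transducer-reflected and
#' wavefront-scattered probe light accumulates as the phonon propagates.
#'
#' @param medium An [acoustic_medium()] (or data frame of media rows with
#'   columns `refractive_index` and `sound_velocity`; vectorised).
#' @param probe_wavelength Probe vacuum wavelength in m.
#' @return Brillouin frequency in Hz.
#' @examples
#' brillouin_frequency(acoustic_medium("w", 1.33, 1000, 1500), 830e-9)
#' @export
brillouin_frequency <- function(medium, probe_wavelength) {
  check_number(probe_wavelength, "probe_wavelength", lower = 0, strict = TRUE)
  m <- as_medium_fields(medium)
  2 * m$refractive_index * m$sound_velocity / probe_wavelength
}

#' Sound velocity from a measured Brillouin shift
#'
#' Exact inverse of [brillouin_frequency()]: \eqn{v = f_B \lambda / (2 n)}.
#'
#' @param f_B Brillouin frequency in Hz, non-negative.
#' @param refractive_index Refractive index of the medium, at least 1.
#' @param probe_wavelength Probe vacuum wavelength in m.
#' @return Sound velocity in m/s.
#' @export
sound_velocity_from_shift <- function(f_B, refractive_index, probe_wavelength) {
  check_number(f_B, "f_B", lower = 0)
  check_number(refractive_index, "refractive_index", lower = 1)
  check_number(probe_wavelength, "probe_wavelength", lower = 0, strict = TRUE)
  f_B * probe_wavelength / (2 * refractive_index)
}

#' Bragg-matched acoustic wavelength
#'
#' The phonon wavelength selected by backscattering Bragg matching,
#' \eqn{\lambda_{acoustic} = \lambda_{probe} / (2n)}.
#'
#' @inheritParams sound_velocity_from_shift
#' @return Acoustic wavelength in m.
#' @examples
#' acoustic_wavelength(830e-9, 1.33) # ~312 nm
#' @export
acoustic_wavelength <- function(probe_wavelength, refractive_index) {
  check_number(probe_wavelength, "probe_wavelength", lower = 0, strict = TRUE)
  check_number(refractive_index, "refractive_index", lower = 1)
  probe_wavelength / (2 * refractive_index)
}

#' Complex longitudinal modulus from Brillouin observables
#'
#' \deqn{M^*(f_B) = M' + iM'' = v^2\rho + i\,\alpha\rho v^3/(\pi f_B)}
#' The storage part is set by sound velocity and density; the loss part adds
#' the phonon attenuation and describes energy dissipated during uni-axial
#' compression at the Brillouin frequency.
#'
#' @param medium An [acoustic_medium()].
#' @param f_B Brillouin frequency in Hz. Must be positive whenever the medium
#'   attenuation is positive (the loss term diverges at zero frequency).
#' @return A list of class `complex_modulus` with components `storage` and
#'   `loss`, both in Pa.
#' @export
longitudinal_modulus <- function(medium, f_B) {
  m <- as_medium_fields(medium)
  check_number(f_B, "f_B", lower = 0)
  if (any(m$attenuation > 0) && any(f_B == 0)) {
    stop_invalid("`f_B` must be positive when the medium attenuation is positive.")
  }
  storage <- m$sound_velocity^2 * m$mass_density
  loss <- if (all(m$attenuation == 0)) {
    rep(0, length(storage))
  } else {
    m$attenuation * m$mass_density * m$sound_velocity^3 / (pi * f_B)
  }
  structure(list(storage = storage, loss = loss), class = "complex_modulus")
}

#' @export
print.complex_modulus <- function(x, ...) {
  cat(sprintf(
    "<complex_modulus> M' = %.4g GPa, M'' = %.4g MPa\n",
    x$storage / 1e9, x$loss / 1e6
  ))
  invisible(x)
}

#' Nominal axial resolution of a windowed depth analysis
#'
#' Two samples one half-window apart are nominally resolvable, so the nominal
#' axial resolution is half the depth full-width-half-maximum of the analysis
#' window: a 520 nm window resolves 260 nm, a 1.28 um window resolves 640 nm.
#'
#' @param window_fwhm Window FWHM mapped to depth, in m, positive.
#' @return Nominal axial resolution in m.
#' @export
nominal_axial_resolution <- function(window_fwhm) {
  check_number(window_fwhm, "window_fwhm", lower = 0, strict = TRUE)
  window_fwhm / 2
}

#' Relative stiffness change implied by a Brillouin shift
#'
#' With refractive index and density unavailable at sub-micrometre scales,
#' the relative Brillouin shift serves as a sound-velocity proxy for relative
#' stiffness: \eqn{100\,\Delta f_B / f_B^0} percent. Sign is preserved; a
#' negative shift indicates a softer region than the baseline medium.
#'
#' @param delta_f Brillouin shift relative to baseline, in Hz.
#' @param baseline_f Baseline (control medium) Brillouin frequency in Hz,
#'   positive.
#' @return Percent change, numeric.
#' @examples
#' fb0 <- brillouin_frequency(acoustic_medium("pbs", 1.33, 1000, 1500), 830e-9)
#' relative_stiffness_percent(600e6, fb0)  # ~12 percent stiffer
#' relative_stiffness_percent(-200e6, fb0) # ~-4 percent softer
#' @export
relative_stiffness_percent <- function(delta_f, baseline_f) {
  check_number(baseline_f, "baseline_f", lower = 0, strict = TRUE)
  if (!is.numeric(delta_f) || anyNA(delta_f)) {
    stop_invalid("`delta_f` must be numeric and non-missing.")
  }
  100 * delta_f / baseline_f
}

#' Effective detection bandwidth of an asynchronous-sampling system
#'
#' Asynchronous optical sampling stretches the pump-probe delay sweep onto a
#' slow laboratory time axis, multiplying the electronic detector bandwidth
#' by the time-stretch factor (repetition rate x sweep duration). A 5.5 MHz
#' detector with an 80 MHz repetition rate swept every 100 us therefore
#' resolves 44 GHz of signal bandwidth.
#'
#' @param detector_bandwidth Electronic detector bandwidth in Hz.
#' @param repetition_rate Laser repetition rate in Hz.
#' @param sweep_duration Laboratory duration of one full delay sweep in s.
#' @return Effective detection bandwidth in Hz.
#' @export
effective_detection_bandwidth <- function(detector_bandwidth,
                                          repetition_rate = 80e6,
                                          sweep_duration = 100e-6) {
  check_number(detector_bandwidth, "detector_bandwidth", lower = 0, strict = TRUE)
  check_number(repetition_rate, "repetition_rate", lower = 0, strict = TRUE)
  check_number(sweep_duration, "sweep_duration", lower = 0, strict = TRUE)
  detector_bandwidth * repetition_rate * sweep_duration
}
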