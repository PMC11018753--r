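#' Attenuation-compensate the control-frequency amplitude channel
#'
#' The surface is found from the roll-off of the wavelet-coefficient
#' amplitude at the control medium's Brillouin frequency. Before the
#' roll-off can be located, the acoustic attenuation of the control medium
#' is divided out: \eqn{C'(t) = \hat A \cdot \hat C} with
#' \eqn{A(t) = \exp(\alpha_{med} v_{med} t)}, each factor normalised by its
#' own maximum over the window. In pure control medium the compensated
#' amplitude is flat (up to noise).
#'
#' @param medium_band_amplitude Amplitude samples at the control frequency
#'   over time (vector), e.g. from [medium_band_amplitude()].
#' @param time Matching time samples in s.
#' @param alpha_med Control amplitude attenuation in 1/m, non-negative.
#' @param v_med Control sound velocity in m/s.
#' @return Compensated amplitude vector \eqn{\hat A \hat C}; in pure control
#'   medium it is constant (flat at its own maximum).
#' @export
compensate_amplitude <- function(medium_band_amplitude, time, alpha_med, v_med) {
  check_number(alpha_med, "alpha_med", lower = 0)
  check_number(v_med, "v_med", lower = 0, strict = TRUE)
  amp <- medium_band_amplitude
  ok <- is.finite(amp)
  if (!any(ok) || max(amp[ok]) <= 0) {
    stop_invalid("Amplitude channel is all zero or missing.")
  }
  A <- exp(alpha_med * v_med * (time - time[1]))
  A_hat <- A / max(A[ok])
  C_hat <- amp / max(amp[ok])
  A_hat * C_hat
}

#' Amplitude channel at the reference frequency
#'
#' The wavelet-coefficient magnitude at the grid frequency nearest the
#' control medium's Brillouin frequency, averaged over +/- 1 grid step.
#'
#' @param spectrogram A `trbs_spectrogram`.
#' @param f_ref Control-medium Brillouin frequency in Hz.
#' @return Numeric vector over depth samples (`NA` at invalid margins).
#' @export
medium_band_amplitude <- function(spectrogram, f_ref) {
  fg <- spectrogram$frequency
  i <- which.min(abs(fg - f_ref))
  rows <- max(1L, i - 1L):min(length(fg), i + 1L)
  out <- colMeans(spectrogram$coefficients[rows, , drop = FALSE])
  out[!spectrogram$valid] <- NA_real_
  out
}

#' Locate the specimen surface from the amplitude roll-off
#'
#' Finds the depth where the compensated, normalised control-frequency
#' amplitude \eqn{C'} falls through the half-contrast level
#' \eqn{\tfrac12(1 + \hat C'_{min})} on its descending roll-off, locating
#' the crossing by linear interpolation between the bracketing samples.
#' When the total contrast \eqn{1 - \hat C'_{min}} is below `min_contrast`
#' no specimen is in range and `found` is `FALSE`. With several descending
#' crossings the first is taken and the quality down-weighted. The
#' alternative `"centroid"` estimator returns the amplitude-derivative
#' centroid of the roll-off.
#'
#' @param compensated Compensated amplitude from [compensate_amplitude()].
#' @param depth_axis Matching depths in m.
#' @param min_contrast Minimum contrast treated as a detection (default 0.2).
#' @param method `"halfmax"` (default) or `"centroid"`.
#' @param transition_width Expected width of the roll-off in m (typically
#'   the analysis window FWHM). When positive, the roll-off floor is
#'   re-measured just beyond the first-pass crossing instead of at the
#'   global minimum, which removes the late bias that residual attenuation
#'   mismatch beyond the surface otherwise induces.
#' @return A one-row tibble (class `surface_result`): `z_p` (m, `NA` when
#'   not found), `quality` in \[0, 1\], `found`.
#' @export
detect_surface <- function(compensated, depth_axis, min_contrast = 0.2,
                           method = c("halfmax", "centroid"),
                           transition_width = 520e-9) {
  method <- match.arg(method)
  ok <- is.finite(compensated)
  x <- compensated[ok]
  z <- depth_axis[ok]
  if (length(x) < 3) stop_invalid("Too few valid samples for surface detection.")
  x <- x / max(x)
  cmin <- min(x)
  contrast <- 1 - cmin
  if (contrast < min_contrast) {
    return(new_surface_result(NA_real_, 0, FALSE))
  }
  cross_at <- function(level) {
    below <- x < level
    which(!below[-length(x)] & below[-1]) # descending crossings
  }
  crossings <- cross_at(0.5 * (1 + cmin))
  if (length(crossings) == 0) {
    return(new_surface_result(NA_real_, 0, FALSE))
  }
  floor_val <- cmin
  if (method == "halfmax" && transition_width > 0) {
    # second pass: floor from just past the transition, not the record end
    z1 <- z[crossings[1]]
    post <- z >= z1 + 0.5 * transition_width &
      z <= z1 + 1.5 * transition_width
    if (sum(post) >= 3) {
      floor_val <- max(cmin, min(1, stats::median(x[post])))
      crossings <- cross_at(0.5 * (1 + floor_val))
      if (length(crossings) == 0) {
        floor_val <- cmin
        crossings <- cross_at(0.5 * (1 + floor_val))
      }
    }
  }
  level <- 0.5 * (1 + floor_val)
  quality <- contrast * if (length(crossings) > 1) 0.5 else 1
  if (method == "halfmax") {
    i <- crossings[1]
    frac <- (x[i] - level) / (x[i] - x[i + 1])
    z_p <- z[i] + frac * (z[i + 1] - z[i])
  } else {
    d <- -diff(x)
    d[d < 0] <- 0
    zm <- (z[-1] + z[-length(z)]) / 2
    z_p <- sum(zm * d) / sum(d)
  }
  new_surface_result(z_p, min(1, quality), TRUE)
}

new_surface_result <- function(z_p, quality, found) {
  out <- tibble(z_p = z_p, quality = quality, found = found)
  class(out) <- c("surface_result", class(out))
  out
}

#' Surface position from one raw trace
#'
#' Pipeline convenience: detrend, wavelet-transform, take the control-band
#' amplitude, compensate for control attenuation and detect the roll-off.
#'
#' @param trace A raw `tof_trace`.
#' @param spec A [wavelet_spec()].
#' @param control Control [acoustic_medium()].
#' @param alpha_med Control attenuation in 1/m; defaults to the medium's own.
#' @param detrend A [detrend_spec()].
#' @param max_depth Analysis depth cap in m.
#' @param probe_wavelength Probe vacuum wavelength in m.
#' @param ... Passed to [detect_surface()].
#' @return A one-row `surface_result` tibble.
#' @export
profile_surface <- function(trace, spec = wavelet_spec(),
                            control = preset_medium("water"),
                            alpha_med = control$attenuation,
                            detrend = detrend_spec(),
                            max_depth = 6e-6,
                            probe_wavelength = 830e-9, ...) {
  det <- remove_background(trace, detrend)
  spg <- cwt_spectrogram(det, spec, max_depth)
  f_ref <- brillouin_frequency(control, probe_wavelength)
  amp <- medium_band_amplitude(spg, f_ref)
  comp <- compensate_amplitude(amp, spg$time, alpha_med, control$sound_velocity)
  detect_surface(comp, spg$depth, transition_width = spec$window_fwhm_z, ...)
}

#' Assemble a topography map from per-position surface results
#'
#' Specimen height is the tip height minus the detected surface stand-off;
#' positions without a detection are `NA`.
#'
#' @param surfaces Tibble with columns `ix`, `iy`, `z_p`, `found` (one row
#'   per lateral position), e.g. row-bound [profile_surface()] results.
#' @param tip_height Tip-to-substrate distance in m.
#' @return A tibble `ix`, `iy`, `height` (m).
#' @export
height_map <- function(surfaces, tip_height) {
  check_number(tip_height, "tip_height", lower = 0, strict = TRUE)
  dplyr::transmute(
    surfaces,
    ix = .data$ix, iy = .data$iy,
    height = ifelse(.data$found, tip_height - .data$z_p, NA_real_)
  )
}
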