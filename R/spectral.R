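#' Background-removal specification
#'
#' The raw reflectivity trace superimposes the Brillouin oscillation on a
#' coincidence transient and a slow thermal decay. Detrending drops an
#' initial exclusion window around the coincidence peak and subtracts a
#' least-squares polynomial capturing the thermal background.
#'
#' @param poly_order Polynomial order (>= 1). Default 5.
#' @param coincidence_exclusion Initial time window removed before fitting,
#'   in s (default 50 ps).
#' @return An object of class `detrend_spec`.
#' @export
detrend_spec <- function(poly_order = 5, coincidence_exclusion = 50e-12) {
  check_number(poly_order, "poly_order", lower = 1)
  check_number(coincidence_exclusion, "coincidence_exclusion", lower = 0)
  structure(
    list(
      poly_order = as.integer(poly_order),
      coincidence_exclusion = coincidence_exclusion
    ),
    class = "detrend_spec"
  )
}

#' Remove the coincidence and thermal background from a trace
#'
#' Drops all samples before the coincidence-exclusion time and subtracts a
#' least-squares polynomial of the configured order; the result oscillates
#' about zero. Applying the operation twice is (numerically) the same as
#' applying it once.
#'
#' @param trace A `tof_trace` (or tibble with `time` and `amplitude`).
#' @param spec A [detrend_spec()].
#' @return A detrended `tof_trace`; metadata attributes are preserved and
#'   `detrended` is set to `TRUE`.
#' @export
remove_background <- function(trace, spec = detrend_spec()) {
  if (!all(c("time", "amplitude") %in% names(trace))) {
    stop_invalid("`trace` must have `time` and `amplitude` columns.")
  }
  keep <- trace$time >= spec$coincidence_exclusion
  if (sum(keep) <= spec$poly_order + 1) {
    stop_invalid("Exclusion window leaves too few samples to detrend.")
  }
  tt <- trace$time[keep]
  amp <- trace$amplitude[keep]
  ts <- (tt - mean(tt)) / stats::sd(tt) # conditioning
  X <- cbind(1, stats::poly(ts, spec$poly_order, raw = FALSE))
  fit <- stats::lm.fit(X, amp)
  out <- new_tof_trace(
    tt, unname(fit$residuals),
    attr(trace, "config"), attr(trace, "position"), attr(trace, "truth")
  )
  attr(out, "detrended") <- TRUE
  out
}

#' Depth-averaged Brillouin shift by FFT peak
#'
#' Finds the in-band peak of the FFT magnitude spectrum and refines it by
#' three-point parabolic interpolation on the log-magnitude, reaching
#' precision well below the 1/T grid for clean signals. Ties between equal
#' peaks resolve to the lower frequency.
#'
#' @param trace A detrended `tof_trace`.
#' @param search_band Two-element frequency interval in Hz, inside Nyquist.
#' @return Peak frequency in Hz.
#' @export
fft_brillouin_shift <- function(trace, search_band = c(3e9, 8e9)) {
  tt <- trace$time
  x <- trace$amplitude
  n <- length(x)
  if (n < 8) stop_invalid("Trace too short.")
  dt <- tt[2] - tt[1]
  nyquist <- 0.5 / dt
  if (length(search_band) != 2 || diff(search_band) <= 0) {
    stop_invalid("`search_band` must be an increasing frequency interval.")
  }
  if (search_band[2] > nyquist) {
    stop_invalid("`search_band` exceeds the Nyquist frequency.")
  }
  freqs <- (seq_len(n) - 1) / (n * dt)
  mag <- Mod(fft(x))
  sel <- which(freqs >= search_band[1] & freqs <= search_band[2])
  if (length(sel) == 0) stop_invalid("`search_band` contains no FFT bins.")
  i <- sel[which.max(mag[sel])] # which.max: first max = lowest frequency
  if (i > 1 && i < n && mag[i - 1] > 0 && mag[i + 1] > 0 && mag[i] > 0) {
    d <- parabolic_offset(log(mag[(i - 1):(i + 1)]))
  } else {
    d <- 0
  }
  (i - 1 + d) / (n * dt)
}

#' Amplitude-weighted mean Brillouin frequency of a spectrogram
#'
#' The coefficient-magnitude-weighted mean frequency over all valid
#' (frequency, depth) cells -- the scalar used for approach curves, where a
#' specimen entering the depth range pulls the weighted average away from
#' the control-medium baseline.
#'
#' @param spectrogram A `trbs_spectrogram` from [cwt_spectrogram()].
#' @return Weighted mean frequency in Hz.
#' @export
weighted_average_shift <- function(spectrogram) {
  C <- spectrogram$coefficients[, spectrogram$valid, drop = FALSE]
  if (length(C) == 0 || sum(C) == 0) {
    stop_invalid("Spectrogram has no non-zero valid coefficients.")
  }
  sum(spectrogram$frequency * rowSums(C)) / sum(C)
}

#' Estimate control-medium phonon attenuation from reference traces
#'
#' With the fibre tip far from any specimen the Brillouin envelope decays as
#' \eqn{\exp(-\alpha v t)}. The quadrature (analytic-signal) envelope is
#' computed per detrended trace, averaged across traces, and fitted by
#' log-linear least squares over a depth window; the slope divided by the
#' control sound velocity is \eqn{\alpha}.
#'
#' @param traces A list of detrended `tof_trace` objects (or a single one).
#' @param control Control [acoustic_medium()] supplying the velocity.
#' @param fit_range Depth window (m) used in the fit, default 0.2--4 um:
#'   clear of detrending edge effects and still within usable signal.
#' @return Estimated amplitude attenuation in 1/m (attribute `velocity`
#'   records the velocity used). A non-decaying envelope yields 0 with a
#'   warning.
#' @export
estimate_attenuation <- function(traces, control, fit_range = c(0.2e-6, 4e-6)) {
  if (inherits(traces, "tof_trace")) traces <- list(traces)
  if (length(traces) == 0) stop_invalid("Need at least one reference trace.")
  v <- control$sound_velocity
  env <- purrr::map(traces, function(tr) analytic_envelope(tr$amplitude))
  env <- Reduce(`+`, env) / length(env)
  tt <- traces[[1]]$time
  z <- v * (tt - tt[1])
  sel <- z >= fit_range[1] & z <= fit_range[2] & env > 0
  if (sum(sel) < 10) stop_invalid("Fit window contains too few samples.")
  fit <- stats::lm.fit(cbind(1, tt[sel]), log(env[sel]))
  slope <- fit$coefficients[2]
  alpha <- -slope / v
  if (alpha < 0) {
    warn("Envelope does not decay over the fit window; returning alpha = 0.")
    alpha <- 0
  }
  structure(unname(alpha), velocity = v)
}
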