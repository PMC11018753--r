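#' Tidy a Gaussian layer fit
#'
#' One row per fitted layer with centre, width (sigma and FWHM) and
#' amplitude in user-friendly units.
#'
#' @param x A `layer_fit` from [fit_layers()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.layer_fit <- function(x, ...) {
  tibble(
    peak = x$peak,
    centre_um = x$centre * 1e6,
    sigma_nm = x$sigma * 1e9,
    fwhm_nm = x$fwhm * 1e9,
    amplitude_mhz = x$amplitude / 1e6
  )
}

#' @rdname tidy.layer_fit
#' @export
glance.layer_fit <- function(x, ...) {
  tibble(
    n_peaks = nrow(x),
    rss = attr(x, "residual"),
    converged = isTRUE(attr(x, "converged"))
  )
}

#' @rdname tidy.layer_fit
#' @param data Unused (fitted values are stored with the object).
#' @export
augment.layer_fit <- function(x, data = NULL, ...) {
  attr(x, "fitted")
}

#' Tidy a depth profile
#'
#' @param x A `depth_profile`.
#' @param ... Unused.
#' @return The profile as a plain tibble with shifts in MHz and depth in um.
#' @export
tidy.depth_profile <- function(x, ...) {
  tibble(
    z_um = x$z * 1e6,
    f_B_ghz = x$f_B / 1e9,
    delta_f_mhz = x$delta_f / 1e6,
    amplitude = x$amplitude,
    valid = x$valid
  )
}

#' Summarise a scan volume
#'
#' @param x A `scan_volume`.
#' @param ... Unused.
#' @return A one-row tibble: grid size, depth samples, valid-voxel count,
#'   shift range.
#' @export
glance.scan_volume <- function(x, ...) {
  v <- x$voxels
  tibble(
    nx = x$nx, ny = x$ny, nz = length(x$depth),
    n_valid = sum(v$valid, na.rm = TRUE),
    delta_f_min = min(v$delta_f[v$valid], na.rm = TRUE),
    delta_f_max = max(v$delta_f[v$valid], na.rm = TRUE)
  )
}
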