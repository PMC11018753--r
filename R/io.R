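# scan container and map exports. The container is a directory of
# plain-text files (CSV payloads + JSON sidecars) so scans survive any
# toolchain: raw_traces.csv [ix, iy, time, amplitude], config.json,
# truth_surface.csv, analysis_voxels.csv, analysis_surface.csv,
# provenance.json. All quantities SI; axes are explicit columns.

#' Write a scan (raw traces and/or analysis) to a bundle directory
#'
#' @param x A `tof_scan` from [simulate_scan()] or a `scan_volume` from
#'   [analyze_scan()].
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan_bundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "tof_scan")) {
    long <- tidyr::unnest(
      dplyr::mutate(
        x$traces,
        trace = purrr::map(.data$trace, ~ as_tibble(.x[c("time", "amplitude")]))
      ),
      "trace"
    )
    utils::write.csv(long, file.path(dir, "raw_traces.csv"), row.names = FALSE)
    utils::write.csv(x$surface, file.path(dir, "truth_surface.csv"),
                     row.names = FALSE)
    cfg <- x$config
    cfg$optics <- unclass(cfg$optics)
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else if (inherits(x, "scan_volume")) {
    utils::write.csv(x$voxels, file.path(dir, "analysis_voxels.csv"),
                     row.names = FALSE)
    if (!is.null(x$surface)) {
      utils::write.csv(x$surface, file.path(dir, "analysis_surface.csv"),
                       row.names = FALSE)
    }
    prov <- x$provenance
    if (!is.null(prov)) {
      prov <- purrr::map(prov, function(p) if (is.list(p)) unclass(p) else p)
      if (!is.null(prov$config$optics)) {
        prov$config$optics <- unclass(prov$config$optics)
      }
      jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
  } else {
    stop_invalid("`x` must be a tof_scan or scan_volume.")
  }
  invisible(dir)
}

#' Read a scan bundle directory
#'
#' Reconstructs whatever the bundle holds: raw traces (as a tibble of
#' `tof_trace` objects) and/or an analysed volume.
#'
#' @param dir Bundle directory written by [write_scan_bundle()].
#' @return A list with elements `traces` (tibble `ix`, `iy`, `trace`),
#'   `surface_truth`, `config`, `volume` -- each `NULL` when absent.
#' @export
read_scan_bundle <- function(dir) {
  out <- list(traces = NULL, surface_truth = NULL, config = NULL,
              volume = NULL)
  f <- file.path(dir, "raw_traces.csv")
  if (file.exists(f)) {
    long <- utils::read.csv(f)
    cfgf <- file.path(dir, "config.json")
    out$config <- if (file.exists(cfgf)) jsonlite::read_json(cfgf, simplifyVector = TRUE) else NULL
    nested <- tidyr::nest(dplyr::group_by(long, .data$ix, .data$iy))
    nested <- dplyr::ungroup(nested)
    out$traces <- dplyr::mutate(
      nested,
      trace = purrr::pmap(list(.data$data, .data$ix, .data$iy),
                          function(d, ix, iy) {
        new_tof_trace(d$time, d$amplitude, out$config, c(ix, iy), NULL)
      })
    )[c("ix", "iy", "trace")]
  }
  f <- file.path(dir, "truth_surface.csv")
  if (file.exists(f)) out$surface_truth <- as_tibble(utils::read.csv(f))
  f <- file.path(dir, "analysis_voxels.csv")
  if (file.exists(f)) {
    voxels <- as_tibble(utils::read.csv(f))
    profs <- tidyr::nest(
      dplyr::group_by(voxels, .data$ix, .data$iy), profile = -c("ix", "iy")
    )
    profs <- dplyr::ungroup(profs)
    surf <- file.path(dir, "analysis_surface.csv")
    out$volume <- assemble_volume(
      profs,
      if (file.exists(surf)) as_tibble(utils::read.csv(surf)) else NULL,
      provenance = {
        pf <- file.path(dir, "provenance.json")
        if (file.exists(pf)) jsonlite::read_json(pf, simplifyVector = TRUE) else NULL
      }
    )
  }
  out
}

#' Export a lateral map to 32-bit float TIFF
#'
#' @param map Tibble with `ix`, `iy` and one value column (the last column
#'   is used).
#' @param path Output file path.
#' @param na Value substituted for missing pixels (default 0; TIFF float
#'   samples do not preserve NaN portably).
#' @return `path`, invisibly.
#' @export
export_map_tiff <- function(map, path, na = 0) {
  m <- map_to_matrix(map)
  m[is.na(m)] <- na
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = TRUE)
  invisible(path)
}

#' @rdname export_map_tiff
#' @export
export_map_csv <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}

map_to_matrix <- function(map) {
  value_col <- setdiff(names(map), c("ix", "iy"))
  if (length(value_col) == 0) stop_invalid("`map` has no value column.")
  value_col <- value_col[length(value_col)]
  nx <- max(map$ix)
  ny <- max(map$iy)
  m <- matrix(NA_real_, nrow = ny, ncol = nx)
  m[cbind(map$iy, map$ix)] <- map[[value_col]]
  m
}
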