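#' File input/output
#'
#' Readers and writers for the on-disk formats: single-channel multi-page
#' float TIFF stacks with a JSON sidecar carrying acquisition metadata and
#' the intensity scale (TIFF float storage is defined on [0, 1], so values
#' are scaled on write and restored on read), CSV schedules and trial
#' tables, and 8-bit HSV renderings of angle/patch maps.
#'
#' @name io
#' @keywords internal
NULL

#' Write an imaging stack as float TIFF + JSON sidecar
#'
#' @param stack `imaging_stack`.
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  mx <- max(stack$frames, 1e-12)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(i) stack$frames[, , i] / mx)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none"))
  meta <- list(frame_rate_hz = stack$frame_rate_hz,
               pixel_size_um = stack$pixel_size_um,
               t0_s = stack$t0_s, intensity_scale = mx,
               dim = dim(stack$frames))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an imaging stack written by [write_stack_tiff()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return `imaging_stack`.
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages) * meta$intensity_scale
  imaging_stack(arr, frame_rate_hz = meta$frame_rate_hz,
                pixel_size_um = meta$pixel_size_um, t0_s = meta$t0_s)
}

#' Write a scalar or axial map as float TIFF + JSON sidecar
#'
#' Scalar maps are written as one page (NA as 0, with the mask as a second
#' page); axial maps as three pages (angle/180, amplitude, mask).
#'
#' @param map `scalar_map` or `axial_map`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  if (inherits(map, "scalar_map")) {
    v <- map$values
    v[!map$mask | is.na(v)] <- 0
    lo <- min(v); hi <- max(v)
    scale <- max(hi - lo, 1e-12)
    pages <- list((v - lo) / scale, map$mask * 1)
    meta <- list(type = "scalar", units = map$units, offset = lo,
                 scale = scale)
  } else if (inherits(map, "axial_map")) {
    a <- map$angle_deg / 180
    a[!map$mask | is.na(a)] <- 0
    amp <- map$amplitude
    amp_scale <- max(amp, 1e-12)
    pages <- list(a, amp / amp_scale, map$mask * 1)
    meta <- list(type = "axial", amplitude_scale = amp_scale)
  } else stop("unsupported map type")
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   compression = "none"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a map written by [write_map_tiff()]
#' @param path TIFF path with sidecar.
#' @return `scalar_map` or `axial_map`.
#' @export
read_map_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (meta$type == "scalar") {
    mask <- pages[[2]] > 0.5
    v <- pages[[1]] * meta$scale + meta$offset
    v[!mask] <- NA_real_
    scalar_map(v, mask, units = meta$units)
  } else {
    mask <- pages[[3]] > 0.5
    ang <- pages[[1]] * 180
    ang[!mask] <- NA_real_
    axial_map(ang, pages[[2]] * meta$amplitude_scale, mask)
  }
}

#' Export an HSV rendering of an angle or patch map
#'
#' Hue encodes the angle (or patch id), saturation scales linearly with
#' amplitude up to `max_amplitude`, value is fixed at 1; masked pixels are
#' black. Mirrors the conventional polar-map rendering. Requires the `png`
#' package.
#'
#' @param map `axial_map`, or the list returned by
#'   [retinotopy_argmax_map()].
#' @param path output PNG path.
#' @param max_amplitude amplitude mapped to full saturation (default the map
#'   maximum).
#' @return `path` invisibly, or NULL (with a message) when `png` is
#'   unavailable.
#' @export
export_hsv_png <- function(map, path, max_amplitude = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    message("png package not available: HSV export skipped")
    return(invisible(NULL))
  }
  if (inherits(map, "axial_map")) {
    hue <- map$angle_deg / 180
    amp <- map$amplitude
    mask <- map$mask
  } else {
    ids <- map$patch$values
    hue <- (ids - min(ids, na.rm = TRUE)) /
      max(1, diff(range(ids, na.rm = TRUE)) + 1)
    amp <- map$amplitude$values
    mask <- map$patch$mask
  }
  if (is.null(max_amplitude)) max_amplitude <- max(amp[mask], 1e-12)
  sat <- pmin(pmax(amp / max_amplitude, 0), 1)
  hue[is.na(hue)] <- 0; sat[!mask | is.na(sat)] <- 0
  val <- matrix(1, nrow(hue), ncol(hue)); val[!mask] <- 0
  col <- grDevices::hsv(pmin(pmax(hue, 0), 1), sat, val)
  rgb <- grDevices::col2rgb(col) / 255
  img <- array(0, c(nrow(hue), ncol(hue), 3))
  img[, , 1] <- matrix(rgb[1, ], nrow(hue)); img[, , 2] <- matrix(rgb[2, ], nrow(hue))
  img[, , 3] <- matrix(rgb[3, ], nrow(hue))
  png::writePNG(img, path)
  invisible(path)
}

#' Write / read a stimulus schedule as CSV
#' @param schedule data.frame as produced by [gen_imaging_dataset()].
#' @param path CSV path.
#' @return `path` invisibly (writer) or the schedule data.frame (reader).
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an electrophysiology trial table as CSV
#' @param trials data.frame as produced by [gen_ephys_dataset()].
#' @param path CSV path.
#' @return `path` invisibly (writer) or the trial data.frame (reader).
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
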