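#' Write an image stack to TIFF with a JSON sidecar
#'
#' Channels are written as pages of a 16-bit multi-page TIFF; physical pixel
#' size, channel labels and the intensity scale used for 16-bit packing go to
#' a sidecar JSON next to the TIFF (`<path>.json`).
#'
#' @param image an [image_stack()].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(image, path) {
  if (!inherits(image, "image_stack")) ais_error("image must be an image_stack", "ais_bad_input")
  d <- dim(image$pixels)
  scale <- max(image$pixels, 1e-12)
  pages <- lapply(seq_len(d[1L]), function(ch) image$pixels[ch, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size_um = image$pixel_size,
               channel_labels = as.list(image$channel_labels),
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF file path with its `<path>.json` sidecar.
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    ais_error(sprintf("missing image or sidecar for '%s'", path),
              "ais_missing_file")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * meta$intensity_scale
  image_stack(arr, meta$pixel_size_um, unlist(meta$channel_labels))
}

#' Write / read a polyline ROI as CSV
#'
#' CSV with columns `x_px`, `y_px`, ordered from the somatic end.
#'
#' @param roi a [polyline_roi()].
#' @param path CSV path.
#' @return `path` (write) or a [polyline_roi()] (read).
#' @export
write_roi_csv <- function(roi, path) {
  write.csv(data.frame(x_px = roi$x, y_px = roi$y), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  if (!file.exists(path))
    ais_error(sprintf("ROI file not found: '%s'", path), "ais_missing_file")
  d <- read.csv(path)
  polyline_roi(d$x_px, d$y_px)
}

#' Write / read a sweep set as per-sweep CSVs plus a protocol JSON
#'
#' Each sweep goes to `sweep_<current>pA.csv` (`time_ms`, `voltage_mV`) in
#' `dir`; the protocol (onset, duration, sample rate, currents) to
#' `protocol.json`.
#'
#' @param sweeps a `sweep_set`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or a `sweep_set` (read).
#' @export
write_sweeps <- function(sweeps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cur <- vapply(sweeps$sweeps, `[[`, 0, "current")
  for (s in sweeps$sweeps) {
    write.csv(data.frame(time_ms = s$time, voltage_mV = s$voltage),
              file.path(dir, sprintf("sweep_%+05dpA.csv", as.integer(s$current))),
              row.names = FALSE)
  }
  jsonlite::write_json(list(step_onset_ms = sweeps$protocol$step_onset,
                            step_duration_ms = sweeps$protocol$step_duration,
                            sample_rate_khz = sweeps$sample_rate,
                            currents_pa = cur),
                       file.path(dir, "protocol.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(dir) {
  pj <- file.path(dir, "protocol.json")
  if (!file.exists(pj))
    ais_error(sprintf("protocol.json not found in '%s'", dir),
              "ais_missing_file")
  meta <- jsonlite::read_json(pj, simplifyVector = TRUE)
  sweeps <- lapply(meta$currents_pa, function(I) {
    d <- read.csv(file.path(dir, sprintf("sweep_%+05dpA.csv", as.integer(I))))
    list(current = I, time = d$time_ms, voltage = d$voltage_mV)
  })
  structure(list(sweeps = sweeps,
                 protocol = list(step_onset = meta$step_onset_ms,
                                 step_duration = meta$step_duration_ms),
                 sample_rate = meta$sample_rate_khz, spec = NULL),
            class = "sweep_set")
}
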