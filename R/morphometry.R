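#' Morphometry configuration
#'
#' Parameters of threshold-based extent detection on normalized profiles.
#' The extent of an AIS or node is the run from the first to the last profile
#' position whose normalized fluorescence exceeds `threshold_fraction`
#' (default 40\%), converted to physical units with `pixel_size`
#' (default 0.21 µm/pixel).
#'
#' @param threshold_fraction fraction of the normalized maximum defining the
#'   object (0 < f < 1, default 0.40).
#' @param pixel_size µm per pixel (default 0.21).
#' @param min_extent minimum plausible object length in µm; shorter detections
#'   are flagged, not discarded (default 1.0).
#' @param strict_contiguity if TRUE, fragmented suprathreshold runs are
#'   reported via a qc flag (the first-above/last-above rule is applied either
#'   way, so gaps are bridged).
#' @return an object of class `morphometry_config`.
#' @export
morphometry_config <- function(threshold_fraction = 0.40, pixel_size = 0.21,
                               min_extent = 1.0, strict_contiguity = FALSE) {
  if (!is.numeric(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    ais_error("threshold_fraction must be in (0, 1)", "ais_bad_input")
  if (pixel_size <= 0) ais_error("pixel_size must be > 0", "ais_bad_input")
  structure(list(threshold_fraction = threshold_fraction,
                 pixel_size = pixel_size, min_extent = min_extent,
                 strict_contiguity = strict_contiguity),
            class = "morphometry_config")
}

resolve_channel <- function(profile, channel) {
  if (is.null(channel)) return(1L)
  if (is.character(channel)) {
    idx <- match(channel, profile$channel_labels)
    if (is.na(idx)) ais_error(sprintf("channel '%s' not present", channel),
                              "ais_bad_input")
    return(idx)
  }
  as.integer(channel)
}

#' Detect object extent on a normalized profile
#'
#' Applies the threshold rule: the object starts at the first profile position
#' whose normalized value exceeds the threshold and ends at the last such
#' position. Gaps between suprathreshold runs are bridged (first-above /
#' last-above); `strict_contiguity` adds a `fragmented` flag when runs are
#' interrupted.
#'
#' @param profile a `straightened_profile`.
#' @param cfg a [morphometry_config()].
#' @param channel channel label or index measured (default first channel).
#' @return list with `start_index`, `end_index` (1-based profile indices),
#'   `channel_used`, `qc_flags`. Errors with class `ais_no_object` when no
#'   position is suprathreshold.
#' @export
detect_extent <- function(profile, cfg = morphometry_config(), channel = NULL) {
  if (!inherits(profile, "straightened_profile"))
    ais_error("profile must be a straightened_profile", "ais_bad_input")
  ch <- resolve_channel(profile, channel)
  if (any(startsWith(profile$qc_flags,
                     paste0("no_signal:", profile$channel_labels[ch]))))
    ais_error("channel flagged no_signal; extent detection refused",
              "ais_no_object")
  v <- profile$normalized[ch, ]
  above <- which(v > cfg$threshold_fraction)
  if (length(above) == 0L)
    ais_error("no object detected (no suprathreshold position)", "ais_no_object")
  start <- min(above); end <- max(above)
  qc <- character(0)
  if (start == 1L || end == length(v))
    qc <- c(qc, "trace_too_short")  # trace must extend beyond the object
  if (cfg$strict_contiguity && any(diff(above) > 1L))
    qc <- c(qc, "fragmented")
  list(start_index = start, end_index = end,
       channel_used = profile$channel_labels[ch], qc_flags = qc)
}

#' Measure AIS length and distance to soma
#'
#' Converts the detected extent to physical units: length is the inclusive
#' pixel count times the pixel size; distance to soma is the arclength from
#' the start of the traced line (somatic end) to the first suprathreshold
#' position.
#'
#' @inheritParams detect_extent
#' @return an `ais_measurement`: list with `length` and `distance_to_soma`
#'   (µm), `start_index`, `end_index`, `channel_used`, `qc_flags`.
#' @export
measure_ais <- function(profile, cfg = morphometry_config(), channel = NULL) {
  ext <- detect_extent(profile, cfg, channel)
  px <- cfg$pixel_size
  len <- (ext$end_index - ext$start_index + 1L) * px
  qc <- ext$qc_flags
  if (len < cfg$min_extent) qc <- c(qc, "below_min_extent")
  structure(list(length = len,
                 distance_to_soma = (ext$start_index - 1L) * px,
                 start_index = ext$start_index, end_index = ext$end_index,
                 channel_used = ext$channel_used, qc_flags = qc),
            class = "ais_measurement")
}

#' Measure node-of-Ranvier length
#'
#' The same extent rule applied to node-scale profiles. The measured channel
#' is selectable: ankyrin-G by default, Nav1.6 as the alternative scaffold
#' marker.
#'
#' @inheritParams detect_extent
#' @param channel channel label or index (default `"ankyrin-G"` if present,
#'   else the first channel).
#' @param group_label optional group annotation (e.g. `"GFP+"` / `"GFP-"`).
#' @return a `node_measurement`: list with `length` (µm), indices,
#'   `channel_used`, `group_label`, `qc_flags`.
#' @export
measure_node <- function(profile, cfg = morphometry_config(),
                         channel = NULL, group_label = NA_character_) {
  if (is.null(channel) && "ankyrin-G" %in% profile$channel_labels)
    channel <- "ankyrin-G"
  ext <- detect_extent(profile, cfg, channel)
  len <- (ext$end_index - ext$start_index + 1L) * cfg$pixel_size
  structure(list(length = len, start_index = ext$start_index,
                 end_index = ext$end_index, channel_used = ext$channel_used,
                 group_label = group_label, qc_flags = ext$qc_flags),
            class = "node_measurement")
}

#' Relative AIS length across a time course
#'
#' Normalizes each time point's measured length to the baseline time point,
#' as used for rapid plasticity experiments where an individual AIS is
#' followed during a manipulation. A time point where detection fails is
#' flagged and reported as `NA`, never interpolated.
#'
#' @param profiles list of `straightened_profile`s, one per time point, in
#'   temporal order.
#' @param cfg a [morphometry_config()].
#' @param baseline_index index of the baseline time point (default 1).
#' @param channel channel measured.
#' @return data.frame with columns `time_index`, `length`, `relative_length`,
#'   `qc` (comma-joined flags; `detection_failed` where applicable).
#' @export
relative_length_timecourse <- function(profiles, cfg = morphometry_config(),
                                       baseline_index = 1L, channel = NULL) {
  if (baseline_index < 1L || baseline_index > length(profiles))
    ais_error("baseline_index out of range", "ais_bad_input")
  meas <- lapply(profiles, function(p) {
    tryCatch(measure_ais(p, cfg, channel),
             ais_no_object = function(e) NULL,
             ais_no_contrast = function(e) NULL)
  })
  len <- vapply(meas, function(m) if (is.null(m)) NA_real_ else m$length, 0)
  qc <- vapply(meas, function(m) {
    if (is.null(m)) "detection_failed" else paste(m$qc_flags, collapse = ",")
  }, "")
  base <- len[baseline_index]
  if (is.na(base))
    ais_error("baseline time point has no detection", "ais_no_object")
  data.frame(time_index = seq_along(profiles), length = len,
             relative_length = len / base, qc = qc,
             stringsAsFactors = FALSE)
}
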