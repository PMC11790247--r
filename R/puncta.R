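#' Puncta detection configuration
#'
#' Parameters of the local-maximum puncta detector operating on straightened
#' images: Gaussian smoothing, an intensity floor of background + k·SD
#' (background and SD estimated robustly by median/MAD), and non-maximum
#' suppression at a minimum separation. Defaults suit synaptopodin clusters
#' and vGAT boutons (objects of ~0.4–0.6 µm).
#'
#' @param smoothing_sigma Gaussian smoothing sigma, µm (default 0.15).
#' @param min_separation minimum center-to-center distance, µm (default 0.4).
#' @param intensity_threshold detection floor in background SDs (default 3).
#' @param restrict_to_extent if TRUE, only maxima whose axial position lies
#'   within the supplied AIS extent are counted (default TRUE).
#' @return an object of class `puncta_detection_config`.
#' @export
puncta_detection_config <- function(smoothing_sigma = 0.15,
                                    min_separation = 0.4,
                                    intensity_threshold = 3,
                                    restrict_to_extent = TRUE) {
  if (min_separation <= 0) ais_error("min_separation must be > 0", "ais_bad_input")
  if (smoothing_sigma < 0) ais_error("smoothing_sigma must be >= 0", "ais_bad_input")
  structure(list(smoothing_sigma = smoothing_sigma,
                 min_separation = min_separation,
                 intensity_threshold = intensity_threshold,
                 restrict_to_extent = restrict_to_extent),
            class = "puncta_detection_config")
}

#' Detect fluorescent puncta in a straightened image
#'
#' Smooths the channel, finds strict 8-neighborhood local maxima above
#' background + k·SD, applies non-maximum suppression (strongest first) at
#' `min_separation`, and optionally restricts detections to the measured AIS
#' extent. An empty channel yields a count of 0, not an error. The count is
#' invariant to global intensity scaling because the threshold is built from
#' the image's own background statistics.
#'
#' @param channel numeric matrix (rows = transverse, columns = axial) such as
#'   `generate_puncta_channel()$channel`, or a single channel of a
#'   `straightened_image`.
#' @param extent numeric `c(start, end)` of the AIS extent in µm (required
#'   when `cfg$restrict_to_extent`).
#' @param cfg a [puncta_detection_config()].
#' @param pixel_size µm per pixel (default 0.21).
#' @return a `puncta_set`: list with `count`, `centroids` (data.frame
#'   `axial_um`, `transverse_um`, `peak_intensity`) and `cfg`.
#' @export
detect_puncta <- function(channel, extent = NULL,
                          cfg = puncta_detection_config(),
                          pixel_size = 0.21) {
  if (!is.matrix(channel)) ais_error("channel must be a matrix", "ais_bad_input")
  if (cfg$restrict_to_extent && is.null(extent))
    ais_error("extent required when restrict_to_extent is set", "ais_bad_input")
  sm <- gblur2d(channel, cfg$smoothing_sigma / pixel_size)
  bg <- median(sm)
  sdev <- mad(sm)
  floor_ <- bg + cfg$intensity_threshold * sdev
  nr <- nrow(sm); nc <- ncol(sm)
  empty <- function() structure(list(count = 0L,
                                     centroids = data.frame(axial_um = numeric(0),
                                                            transverse_um = numeric(0),
                                                            peak_intensity = numeric(0)),
                                     cfg = cfg), class = "puncta_set")
  if (nr < 3L || nc < 3L || all(sm <= floor_)) return(empty())
  core <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > floor_
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- sm[2:(nr - 1) + dr, 2:(nc - 1) + dc]
    is_max <- is_max & (core >= nb) & (core > nb | (dr < 0 | (dr == 0 & dc < 0)))
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty())
  rows <- idx[, 1] + 1L
  cols <- idx[, 2] + 1L
  # sub-pixel refinement: 3-point parabola through the peak in each axis
  para <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    ifelse(den == 0, 0, pmax(-0.5, pmin(0.5, 0.5 * (ym - yp) / den)))
  }
  dc <- para(sm[cbind(rows, cols - 1L)], sm[cbind(rows, cols)],
             sm[cbind(rows, cols + 1L)])
  dr <- para(sm[cbind(rows - 1L, cols)], sm[cbind(rows, cols)],
             sm[cbind(rows + 1L, cols)])
  ax <- (cols - 1 + dc) * pixel_size
  tv <- (rows - 1 + dr - (nr - 1) / 2) * pixel_size
  peak <- sm[cbind(rows, cols)]
  # non-maximum suppression, strongest first
  ord <- order(peak, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0L ||
        all(sqrt((ax[keep] - ax[i])^2 + (tv[keep] - tv[i])^2) >=
              cfg$min_separation))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  ax <- ax[keep]; tv <- tv[keep]; peak <- peak[keep]
  if (cfg$restrict_to_extent) {
    inside <- ax >= extent[1] & ax <= extent[2]
    ax <- ax[inside]; tv <- tv[inside]; peak <- peak[inside]
  }
  structure(list(count = length(ax),
                 centroids = data.frame(axial_um = ax, transverse_um = tv,
                                        peak_intensity = peak),
                 cfg = cfg),
            class = "puncta_set")
}

#' Compare puncta counts between two groups
#'
#' Unpaired two-sample t-test on per-AIS counts with group summaries, as used
#' for comparing synaptopodin cluster and vGAT bouton counts between AIS
#' populations.
#'
#' @param group_a,group_b numeric vectors of per-AIS counts (each n >= 2).
#' @param labels length-2 character vector of group names.
#' @return a `comparison_result` (see [compare_groups()]).
#' @export
compare_puncta_counts <- function(group_a, group_b,
                                  labels = c("groupA", "groupB")) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    ais_error("each group needs n >= 2", "ais_bad_input")
  values <- c(group_a, group_b)
  groups <- rep(labels, c(length(group_a), length(group_b)))
  compare_groups(values, groups, force_test = "t")
}
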