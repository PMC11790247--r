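#' Multi-channel image with physical pixel size
#'
#' Container for a 2D multi-channel fluorescence image. Pixels are stored as a
#' numeric array `channel x y x x` (z-stacks are max-projected on construction,
#' matching measurement on projected confocal stacks). All intensities must be
#' non-negative and every channel must share the same shape.
#'
#' @param pixels numeric array; `y x x` matrix for a single channel,
#'   `channel x y x x` for multi-channel, or `channel x y x x x z` for stacks
#'   (max-projected over z).
#' @param pixel_size physical pixel size in µm/pixel (> 0).
#' @param channel_labels character vector naming the channels.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size, channel_labels = NULL) {
  if (!is.numeric(pixels)) ais_error("pixels must be numeric", "ais_bad_input")
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, dim(pixels)))
  }
  if (length(dim(pixels)) == 4L) {  # channel x y x x x z -> max projection
    pixels <- apply(pixels, c(1L, 2L, 3L), max)
  }
  if (length(dim(pixels)) != 3L)
    ais_error("pixels must be a matrix or a channel x y x x array", "ais_bad_input")
  if (any(pixels < 0)) ais_error("intensities must be non-negative", "ais_bad_input")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    ais_error("pixel_size must be a positive scalar (um/pixel)", "ais_bad_input")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(dim(pixels)[1L]))
  if (length(channel_labels) != dim(pixels)[1L])
    ais_error("one label per channel required", "ais_bad_input")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel_labels = as.character(channel_labels)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d channel(s), %d x %d px, %.3g um/px [%s]\n",
              d[1L], d[3L], d[2L], x$pixel_size,
              paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

#' Polyline ROI traced from the somatic end
#'
#' An ordered pixel-coordinate trace drawn from the somatic domain, through the
#' AIS (or node), into the distal axon. The first vertex is by convention the
#' somatic end; arclength positions are measured from it. Coordinates are
#' 0-based pixel centers.
#'
#' @param x,y numeric vectors of vertex coordinates in pixels (>= 2 vertices,
#'   consecutive vertices distinct).
#' @return an object of class `polyline_roi`.
#' @export
polyline_roi <- function(x, y) {
  if (length(x) != length(y)) ais_error("x and y differ in length", "ais_bad_input")
  if (length(x) < 2L) ais_error("polyline needs at least 2 vertices", "ais_bad_input")
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0))
    ais_error("consecutive vertices must be distinct", "ais_degenerate_roi")
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "polyline_roi")
}

#' Total arclength of a polyline ROI
#'
#' @param roi a [polyline_roi()].
#' @return arclength in the ROI's coordinate units (pixels).
#' @export
roi_arclength <- function(roi) sum(sqrt(diff(roi$x)^2 + diff(roi$y)^2))

# Vectorized bilinear sampling of matrix z (rows = y, cols = x) at 0-based
# pixel-center coordinates; NA outside the grid. The tight inner loop of
# straightening, so kept allocation-lean.
bilinear_sample <- function(z, xp, yp) {
  ny <- nrow(z); nx <- ncol(z)
  ok <- xp >= 0 & xp <= nx - 1 & yp >= 0 & yp <= ny - 1
  v <- rep(NA_real_, length(xp))
  if (!any(ok)) return(v)
  x <- xp[ok]; y <- yp[ok]
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + x0 * ny  # column-major linear index of (y0, x0)
  v[ok] <- z[i00] * (1 - fx) * (1 - fy) + z[i00 + ny] * fx * (1 - fy) +
    z[i00 + 1] * (1 - fx) * fy + z[i00 + ny + 1] * fx * fy
  v
}

#' Resample a polyline at uniform arclength spacing
#'
#' Walks the polyline from its somatic end and places points every `spacing`
#' units of arclength (same units as the vertex coordinates). The final point
#' is the last multiple of `spacing` not exceeding the total arclength, so the
#' total length is preserved to within `spacing`.
#'
#' @param roi a [polyline_roi()].
#' @param spacing arclength step, in pixels (> 0).
#' @return a data.frame with columns `x`, `y`, `s` (arclength from the start).
#' @export
resample_path <- function(roi, spacing) {
  if (!inherits(roi, "polyline_roi")) ais_error("roi must be a polyline_roi", "ais_bad_input")
  if (!is.numeric(spacing) || spacing <= 0) ais_error("spacing must be > 0", "ais_bad_input")
  seg <- sqrt(diff(roi$x)^2 + diff(roi$y)^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- seq(0, total, by = spacing)
  x <- approx(cum, roi$x, xout = s)$y
  y <- approx(cum, roi$y, xout = s)$y
  data.frame(x = x, y = y, s = s)
}

#' Straighten an image along a polyline ROI
#'
#' Resamples each channel on a moving frame along the traced path: column `c`
#' of the output is the path point at arclength `c` pixels from the somatic
#' end, rows are offsets along the local unit normal, sampled bilinearly.
#' The result is the axon laid out along one axis with a transverse band of
#' `half_width` on either side.
#'
#' @param image an [image_stack()].
#' @param roi a [polyline_roi()]; coordinates in pixels of `image`.
#' @param half_width transverse half-width of the band in µm (> 0); default 3
#'   pixels.
#' @param spacing_px arclength step along the path in pixels (default 1, i.e.
#'   output columns are one pixel apart so column index equals arclength).
#' @return a `straightened_image`: list with `pixels` (channel x row x column
#'   array, `NA` where the band leaves the image), `pixel_size`,
#'   `channel_labels`, `half_width`.
#' @export
straighten <- function(image, roi, half_width = 3 * image$pixel_size,
                       spacing_px = 1) {
  if (!inherits(image, "image_stack")) ais_error("image must be an image_stack", "ais_bad_input")
  if (!is.numeric(half_width) || half_width <= 0)
    ais_error("half_width must be > 0", "ais_bad_input")
  path <- resample_path(roi, spacing_px)
  n <- nrow(path)
  # local tangents by central differences, one-sided at the ends
  tx <- c(path$x[2] - path$x[1],
          if (n > 2) path$x[3:n] - path$x[1:(n - 2)] else NULL,
          path$x[n] - path$x[n - 1])
  ty <- c(path$y[2] - path$y[1],
          if (n > 2) path$y[3:n] - path$y[1:(n - 2)] else NULL,
          path$y[n] - path$y[n - 1])
  nrm <- sqrt(tx^2 + ty^2)
  nxv <- -ty / nrm  # unit normal
  nyv <- tx / nrm
  hw_px <- max(1L, round(half_width / image$pixel_size))
  off <- seq(-hw_px, hw_px)
  # sample coordinates: rows = offsets, cols = path points
  sx <- outer(off, nxv) + matrix(path$x, nrow = length(off), ncol = n, byrow = TRUE)
  sy <- outer(off, nyv) + matrix(path$y, nrow = length(off), ncol = n, byrow = TRUE)
  d <- dim(image$pixels)
  nx <- d[3L]; ny <- d[2L]
  out <- array(NA_real_, dim = c(d[1L], length(off), n))
  for (ch in seq_len(d[1L])) {
    out[ch, , ] <- bilinear_sample(image$pixels[ch, , ],
                                   as.vector(sx), as.vector(sy))
  }
  if (anyNA(out))
    ais_warn("transverse band leaves the image; clipped samples set to NA",
             "ais_band_clipped")
  structure(list(pixels = out, pixel_size = image$pixel_size,
                 channel_labels = image$channel_labels,
                 half_width = hw_px * image$pixel_size),
            class = "straightened_image")
}

#' Extract a normalized intensity profile from a straightened image
#'
#' Collapses the transverse band to one value per column (default: maximum,
#' robust to slight trace offsets) and min-max normalizes each channel to
#' \[0, 1\]. The baseline is the 1st percentile of the column aggregates
#' (a robust minimum under noise); the maximum maps to 1.
#'
#' @param simg a `straightened_image` from [straighten()], or a plain numeric
#'   matrix (rows = transverse, columns = along the axon) with `pixel_size`.
#' @param aggregation `"max"` (default) or `"mean"` over the transverse band.
#' @param baseline_quantile quantile of column values used as baseline
#'   (default 0.01).
#' @param pixel_size µm/pixel, required when `simg` is a bare matrix.
#' @return a `straightened_profile`: list with `positions` (µm from the trace
#'   start), `intensity` and `normalized` (matrices channel x column),
#'   `channel_labels`, `pixel_size`, `qc_flags`.
#' @export
extract_profile <- function(simg, aggregation = c("max", "mean"),
                            baseline_quantile = 0.01, pixel_size = NULL) {
  aggregation <- match.arg(aggregation)
  if (is.matrix(simg)) {
    if (is.null(pixel_size)) ais_error("pixel_size required for a bare matrix", "ais_bad_input")
    simg <- structure(list(pixels = array(simg, c(1L, dim(simg))),
                           pixel_size = pixel_size, channel_labels = "ch1",
                           half_width = NA_real_),
                      class = "straightened_image")
  }
  px <- simg$pixels
  if (length(px) == 0L) ais_error("empty straightened image", "ais_bad_input")
  nch <- dim(px)[1L]; ncol_ <- dim(px)[3L]
  agg <- matrix(NA_real_, nch, ncol_)
  for (ch in seq_len(nch)) {
    m <- px[ch, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    agg[ch, ] <- if (aggregation == "max") {
      suppressWarnings(apply(m, 2L, max, na.rm = TRUE))
    } else {
      colMeans(m, na.rm = TRUE)
    }
  }
  agg[!is.finite(agg)] <- NA_real_
  qc <- character(0)
  norm <- matrix(NA_real_, nch, ncol_)
  for (ch in seq_len(nch)) {
    v <- agg[ch, ]
    base <- quantile(v, baseline_quantile, na.rm = TRUE, names = FALSE)
    top <- max(v, na.rm = TRUE)
    # contrast below float tolerance counts as constant
    if (!is.finite(top) || top - base <= 1e-9 * max(abs(top), 1)) {
      if (all(v[is.finite(v)] == 0)) {
        qc <- c(qc, sprintf("no_signal:%s", simg$channel_labels[ch]))
        norm[ch, ] <- 0
        next
      }
      ais_error(sprintf("channel '%s' has no contrast (constant profile)",
                        simg$channel_labels[ch]), "ais_no_contrast")
    }
    norm[ch, ] <- pmin(1, pmax(0, (v - base) / (top - base)))
  }
  structure(list(positions = (seq_len(ncol_) - 1L) * simg$pixel_size,
                 intensity = agg, normalized = norm,
                 channel_labels = simg$channel_labels,
                 pixel_size = simg$pixel_size, qc_flags = qc),
            class = "straightened_profile")
}

#' @export
print.straightened_profile <- function(x, ...) {
  cat(sprintf("<straightened_profile> %d channel(s), %d positions, %.3g um/px\n",
              nrow(x$normalized), ncol(x$normalized), x$pixel_size))
  invisible(x)
}

#' Build a straightened profile from a 1-D intensity trace
#'
#' Wraps an already-extracted 1-D intensity vector (e.g. a line profile from
#' other software) as a `straightened_profile` so extent detection and length
#' measurement can run on it. With `normalize = TRUE` the vector is min-max
#' normalized using the 1st percentile as baseline; otherwise it is taken as
#' already normalized.
#'
#' @param v numeric intensity vector, one value per pixel along the axon.
#' @param pixel_size µm per pixel.
#' @param channel channel label.
#' @param normalize normalize the vector (default TRUE).
#' @return a `straightened_profile`.
#' @export
profile_from_vector <- function(v, pixel_size, channel = "ch1", normalize = TRUE) {
  v <- as.numeric(v)
  norm <- if (normalize) {
    base <- quantile(v, 0.01, names = FALSE)
    top <- max(v)
    if (top - base <= 0) ais_error("constant profile", "ais_no_contrast")
    pmin(1, pmax(0, (v - base) / (top - base)))
  } else v
  structure(list(positions = (seq_along(v) - 1L) * pixel_size,
                 intensity = matrix(v, 1L), normalized = matrix(norm, 1L),
                 channel_labels = channel, pixel_size = pixel_size,
                 qc_flags = character(0)),
            class = "straightened_profile")
}
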