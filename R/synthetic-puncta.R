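#' Specification of a synthetic puncta channel
#'
#' Describes discrete fluorescent objects along the AIS — synaptopodin
#' clusters of the cisternal organelle (a few per AIS) or vGAT-positive
#' axo-axonic boutons (~20 per AIS). Counts are Poisson or fixed; centers are
#' placed uniformly along the extent with transverse jitter and a hard
#' minimum center separation, since boutons and clusters are non-overlapping
#' physical objects of roughly one punctum diameter.
#'
#' @param mean_count expected puncta per AIS (>= 0).
#' @param count_model `"poisson"` or `"fixed"`.
#' @param punctum_sigma Gaussian radius of one punctum, µm (default 0.15,
#'   i.e. ~0.35 µm FWHM, a diffraction-limited confocal object).
#' @param punctum_intensity peak intensity, arbitrary units (default 100).
#' @param min_spacing hard minimum center-to-center distance, µm
#'   (default 0.6: one bouton diameter, and above the detector's
#'   grid-limited resolving distance of ~2 sigma + 1 pixel).
#' @param transverse_sd SD of transverse center jitter, µm (default 0.25,
#'   truncated to the rendered band).
#' @param background_intensity constant baseline offset (default 10).
#' @param noise_sd additive Gaussian pixel noise SD (default 2).
#' @return an object of class `puncta_spec`.
#' @export
puncta_spec <- function(mean_count, count_model = c("poisson", "fixed"),
                        punctum_sigma = 0.15, punctum_intensity = 100,
                        min_spacing = 0.6, transverse_sd = 0.25,
                        background_intensity = 10, noise_sd = 2) {
  count_model <- match.arg(count_model)
  if (mean_count < 0) ais_error("mean_count must be >= 0", "ais_bad_input")
  if (punctum_sigma <= 0 || min_spacing <= 0)
    ais_error("punctum_sigma and min_spacing must be > 0", "ais_bad_input")
  structure(list(mean_count = mean_count, count_model = count_model,
                 punctum_sigma = punctum_sigma,
                 punctum_intensity = punctum_intensity,
                 min_spacing = min_spacing, transverse_sd = transverse_sd,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd),
            class = "puncta_spec")
}

#' Generate a synthetic puncta channel in the straightened frame
#'
#' Renders a straightened-frame image (rows = transverse, columns = along the
#' axon) containing `N` Gaussian puncta whose centers lie strictly within the
#' AIS extent. `N` is drawn per `count_model`; placement is uniform along the
#' extent with a hard minimum separation (dart throwing), which always
#' succeeds at the densities of synpo/vGAT objects, so the count distribution
#' is exactly the drawn one.
#'
#' @param extent numeric length-2 vector `c(start, end)` of the AIS extent in
#'   µm along the straightened axis.
#' @param spec a [puncta_spec()].
#' @param seed integer seed.
#' @param pixel_size µm per pixel (default 0.21).
#' @param band_halfwidth transverse half-width of the rendered band, µm.
#' @param axis_length total axial length of the channel, µm (defaults to the
#'   extent end plus a 2 µm margin).
#' @return list with `channel` (matrix rows x cols), `true_count`,
#'   `centers` (data.frame `axial_um`, `transverse_um`), `pixel_size`,
#'   `record` (one-row manifest data.frame).
#' @export
generate_puncta_channel <- function(extent, spec, seed = NULL,
                                    pixel_size = 0.21, band_halfwidth = 0.63,
                                    axis_length = NULL) {
  if (!inherits(spec, "puncta_spec")) ais_error("spec must be a puncta_spec", "ais_bad_input")
  if (length(extent) != 2L || extent[2] <= extent[1])
    ais_error("extent must be c(start, end) with end > start", "ais_bad_input")
  if (is.null(axis_length)) axis_length <- extent[2] + 2
  ncol_ <- floor(axis_length / pixel_size) + 1L
  hw_px <- max(1L, round(band_halfwidth / pixel_size))
  nrow_ <- 2L * hw_px + 1L
  with_seed(seed, {
    n <- switch(spec$count_model,
                poisson = rpois(1L, spec$mean_count),
                fixed = round(spec$mean_count))
    ax <- numeric(0); tv <- numeric(0)
    attempts <- 0L
    # objects are solid: centers stay one punctum radius inside the extent
    # and inside the rendered band, so no punctum straddles a boundary
    inset <- min(spec$punctum_sigma, (extent[2] - extent[1]) / 4)
    t_max <- max(0, band_halfwidth - spec$punctum_sigma)
    while (length(ax) < n) {
      cand_a <- runif(1, extent[1] + inset, extent[2] - inset)
      cand_t <- max(-t_max, min(t_max, rnorm(1, 0, spec$transverse_sd)))
      attempts <- attempts + 1L
      if (attempts > 10000L)
        ais_error("could not place puncta at the requested density",
                  "ais_too_dense")
      if (length(ax) == 0 ||
          all(sqrt((ax - cand_a)^2 + (tv - cand_t)^2) >= spec$min_spacing)) {
        ax <- c(ax, cand_a); tv <- c(tv, cand_t)
      }
    }
    chan <- matrix(spec$background_intensity, nrow_, ncol_)
    if (n > 0) {
      col_um <- (seq_len(ncol_) - 1L) * pixel_size
      row_um <- (seq_len(nrow_) - 1L - hw_px) * pixel_size
      for (i in seq_len(n)) {
        chan <- chan + spec$punctum_intensity *
          outer(exp(-(row_um - tv[i])^2 / (2 * spec$punctum_sigma^2)),
                exp(-(col_um - ax[i])^2 / (2 * spec$punctum_sigma^2)))
      }
    }
    if (spec$noise_sd > 0) {
      chan <- chan + matrix(rnorm(length(chan), 0, spec$noise_sd), nrow_)
      chan[chan < 0] <- 0
    }
    list(channel = chan, true_count = n,
         centers = data.frame(axial_um = ax, transverse_um = tv),
         pixel_size = pixel_size,
         record = data.frame(true_count = n, mean_count = spec$mean_count,
                             count_model = spec$count_model,
                             extent_start = extent[1], extent_end = extent[2],
                             seed = if (is.null(seed)) NA_integer_ else seed,
                             stringsAsFactors = FALSE))
  })
}
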