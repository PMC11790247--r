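#' Ground-truth description of one synthetic AIS
#'
#' Parameters of a single rendered AIS: a plateau of fluorescence along a
#' curved axonal path, starting `true_distance_to_soma` µm of arclength from
#' the somatic end of the trace and extending for `true_length` µm, over a
#' background, with optional smooth (error-function) edges, isotropic PSF
#' blur and additive Gaussian pixel noise.
#'
#' @param true_length AIS length in µm (> 0).
#' @param true_distance_to_soma arclength from trace start to AIS onset, µm.
#' @param pixel_size µm per pixel (default 0.21).
#' @param plateau_intensity plateau level, arbitrary units.
#' @param background_intensity background level (< plateau).
#' @param noise_sd SD of additive Gaussian pixel noise, same units.
#' @param psf_sigma isotropic Gaussian PSF sigma in µm (0 = no blur).
#' @param edge_rise 10–90\% rise length of the plateau edges in µm; 0 gives
#'   ideal sharp (half-open) edges (default 0.5).
#' @param axon_sigma transverse Gaussian radius of the axon in µm.
#' @param distal_margin trace continues this far beyond the AIS end, µm.
#' @param wiggle_amplitude,wiggle_period amplitude (µm) and period (µm) of the
#'   sinusoidal transverse meander giving the path its curvature.
#' @param path_control_points optional data.frame `x`,`y` (pixels) overriding
#'   the synthesized path; arclength along it parameterizes the plateau.
#' @return an object of class `ais_ground_truth`.
#' @export
ais_ground_truth <- function(true_length,
                             true_distance_to_soma = 5,
                             pixel_size = 0.21,
                             plateau_intensity = 100,
                             background_intensity = 10,
                             noise_sd = 5,
                             psf_sigma = 0,
                             edge_rise = 0.5,
                             axon_sigma = 0.3,
                             distal_margin = 8,
                             wiggle_amplitude = 1.5,
                             wiggle_period = 25,
                             path_control_points = NULL) {
  if (!is.numeric(true_length) || true_length <= 0)
    ais_error("true_length must be > 0", "ais_bad_input")
  if (true_distance_to_soma < 0)
    ais_error("true_distance_to_soma must be >= 0", "ais_bad_input")
  if (pixel_size <= 0) ais_error("pixel_size must be > 0", "ais_bad_input")
  if (plateau_intensity <= background_intensity)
    ais_error("plateau_intensity must exceed background_intensity (degenerate contrast)",
              "ais_degenerate_contrast")
  if (noise_sd < 0 || psf_sigma < 0 || edge_rise < 0)
    ais_error("noise_sd, psf_sigma and edge_rise must be >= 0", "ais_bad_input")
  structure(list(true_length = true_length,
                 true_distance_to_soma = true_distance_to_soma,
                 pixel_size = pixel_size,
                 plateau_intensity = plateau_intensity,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, psf_sigma = psf_sigma,
                 edge_rise = edge_rise, axon_sigma = axon_sigma,
                 distal_margin = distal_margin,
                 wiggle_amplitude = wiggle_amplitude,
                 wiggle_period = wiggle_period,
                 path_control_points = path_control_points),
            class = "ais_ground_truth")
}

# Synthesize a gently meandering path of the requested arclength (um),
# returned as pixel-coordinate vertices spaced ~1 px with exact cumulative
# arclength reparameterization (vertices every step of true arclength).
synth_path <- function(total_um, gt, margin_px = 6) {
  px <- gt$pixel_size
  if (!is.null(gt$path_control_points)) {
    p <- gt$path_control_points
    return(polyline_roi(p$x, p$y))
  }
  amp_px <- gt$wiggle_amplitude / px
  per_px <- gt$wiggle_period / px
  # param curve x = t, y = amp sin(2 pi t / per); re-parameterize by arclength
  t_fine <- seq(0, 2 * total_um / px, by = 0.25)
  y_fine <- amp_px * sin(2 * pi * t_fine / per_px)
  seg <- sqrt(diff(t_fine)^2 + diff(y_fine)^2)
  cum <- c(0, cumsum(seg))
  total_px <- total_um / px
  s_want <- seq(0, total_px, by = 1)
  xs <- approx(cum, t_fine, xout = s_want)$y
  ys <- approx(cum, y_fine, xout = s_want)$y
  polyline_roi(xs + margin_px, ys + margin_px + amp_px)
}

# Axial plateau profile at arclength s (um): sharp half-open interval when
# edge_rise = 0, erf edges with sigma = edge_rise/2 otherwise (so edge_rise
# approximates the 10-90% rise length).
axial_profile <- function(s, gt) {
  on <- gt$true_distance_to_soma
  off <- on + gt$true_length
  if (gt$edge_rise == 0) {
    as.numeric(s >= on & s < off)
  } else {
    sig <- gt$edge_rise / 2
    pnorm((s - on) / sig) - pnorm((s - off) / sig)
  }
}

# Separable Gaussian blur (reflective edges) used for the PSF.
gblur2d <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(r)]), v, rev(v[(n - r + 1):n]))
    as.numeric(stats::filter(vp, k, sides = 2))[(r + 1):(r + n)]
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(t(m), 2L, pad_conv))
}

#' Render a synthetic AIS image with its ROI trace
#'
#' Renders the ground-truth model onto a pixel canvas sized to contain the
#' path plus margins: intensity at a pixel is background plus
#' (plateau − background) × axial profile at the pixel's arclength × a
#' transverse Gaussian falloff from the path, followed by optional PSF blur
#' and additive Gaussian noise (clipped at zero). The returned ROI is the
#' generating path itself, traced from the somatic end, starting proximal to
#' the AIS onset and ending distal to its end.
#'
#' @param gt an [ais_ground_truth()].
#' @param seed integer seed for the noise draw (NULL = use current RNG state).
#' @param id object identifier recorded in the manifest record.
#' @return list with `image` ([image_stack()]), `roi` ([polyline_roi()]) and
#'   `record` (one-row data.frame of ground-truth parameters).
#' @export
generate_ais_image <- function(gt, seed = NULL, id = "ais_1") {
  if (!inherits(gt, "ais_ground_truth"))
    ais_error("gt must be an ais_ground_truth", "ais_bad_input")
  px <- gt$pixel_size
  total_um <- gt$true_distance_to_soma + gt$true_length + gt$distal_margin
  roi <- synth_path(total_um, gt)
  margin <- 6
  nx <- ceiling(max(roi$x)) + margin
  ny <- ceiling(max(roi$y)) + margin
  if (min(roi$x) < 0 || min(roi$y) < 0 || max(roi$x) > nx || max(roi$y) > ny)
    ais_error("path exits the image canvas", "ais_path_outside")
  # distance + arclength of nearest path point for every pixel near the path,
  # by projection onto ~5 px segments of the resampled path
  seg_pts <- resample_path(roi, 5)
  n_seg <- nrow(seg_pts) - 1L
  gx <- rep(0:(nx - 1), each = ny)   # column-major: y fastest
  gy <- rep(0:(ny - 1), times = nx)
  best_d2 <- rep(Inf, nx * ny)
  best_s <- rep(NA_real_, nx * ny)
  for (i in seq_len(n_seg)) {
    ax <- seg_pts$x[i]; ay <- seg_pts$y[i]
    bx <- seg_pts$x[i + 1]; by <- seg_pts$y[i + 1]
    ux <- bx - ax; uy <- by - ay
    L2 <- ux^2 + uy^2
    t <- pmin(1, pmax(0, ((gx - ax) * ux + (gy - ay) * uy) / L2))
    dx <- gx - (ax + t * ux); dy <- gy - (ay + t * uy)
    d2 <- dx^2 + dy^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- (seg_pts$s[i] + t[upd] * sqrt(L2)) * px
  }
  ax_prof <- axial_profile(best_s, gt)
  trans <- exp(-best_d2 * px^2 / (2 * gt$axon_sigma^2))
  img <- matrix(gt$background_intensity +
                  (gt$plateau_intensity - gt$background_intensity) *
                  ax_prof * trans,
                nrow = ny, ncol = nx)
  if (gt$psf_sigma > 0) img <- gblur2d(img, gt$psf_sigma / px)
  if (gt$noise_sd > 0) {
    img <- with_seed(seed, img + matrix(rnorm(length(img), 0, gt$noise_sd),
                                        nrow = ny))
    img[img < 0] <- 0
  }
  record <- data.frame(id = id, true_length = gt$true_length,
                       true_distance_to_soma = gt$true_distance_to_soma,
                       pixel_size = px,
                       plateau_intensity = gt$plateau_intensity,
                       background_intensity = gt$background_intensity,
                       noise_sd = gt$noise_sd, psf_sigma = gt$psf_sigma,
                       edge_rise = gt$edge_rise,
                       seed = if (is.null(seed)) NA_integer_ else seed,
                       stringsAsFactors = FALSE)
  list(image = image_stack(img, px, "ankG-GFP"), roi = roi, record = record)
}

#' Condition specification for a hierarchical AIS population
#'
#' Describes one experimental condition of the organotypic-culture plasticity
#' design: `n_otc` cultures, `n_ais_per_otc` AIS each, with per-AIS true
#' lengths drawn as `mean_length` + OTC offset (Normal(0, `between_otc_sd`))
#' + Normal(0, `sd_length`).
#'
#' @param name condition label.
#' @param mean_length,sd_length population mean and between-AIS SD of true
#'   length, µm.
#' @param n_otc number of cultures (default 6).
#' @param n_ais_per_otc AIS per culture (default 50).
#' @param between_otc_sd SD of the per-OTC offset, µm (default 0).
#' @return an object of class `condition_spec`.
#' @export
condition_spec <- function(name, mean_length, sd_length, n_otc = 6L,
                           n_ais_per_otc = 50L, between_otc_sd = 0) {
  if (n_otc < 1L || n_ais_per_otc < 1L)
    ais_error("n_otc and n_ais_per_otc must be >= 1", "ais_bad_input")
  if (sd_length < 0 || between_otc_sd < 0)
    ais_error("SDs must be >= 0", "ais_bad_input")
  structure(list(name = name, mean_length = mean_length,
                 sd_length = sd_length, n_otc = as.integer(n_otc),
                 n_ais_per_otc = as.integer(n_ais_per_otc),
                 between_otc_sd = between_otc_sd),
            class = "condition_spec")
}

#' Draw the ground-truth lengths of a condition population
#'
#' Samples the hierarchical length model of [condition_spec()] without
#' rendering images. Draws are clipped to a small positive floor; clipping
#' affecting more than 1\% of draws triggers a warning.
#'
#' @param spec a [condition_spec()].
#' @param seed integer seed.
#' @return data.frame with columns `condition`, `otc`, `ais`, `true_length`.
#' @export
draw_condition_lengths <- function(spec, seed = NULL) {
  if (!inherits(spec, "condition_spec"))
    ais_error("spec must be a condition_spec", "ais_bad_input")
  with_seed(seed, {
    otc_off <- rnorm(spec$n_otc, 0, spec$between_otc_sd)
    n <- spec$n_otc * spec$n_ais_per_otc
    len <- spec$mean_length + rep(otc_off, each = spec$n_ais_per_otc) +
      rnorm(n, 0, spec$sd_length)
    clipped <- len < 1
    if (mean(clipped) > 0.01)
      ais_warn(sprintf("%.1f%% of length draws clipped at 1 um",
                       100 * mean(clipped)), "ais_clipping")
    len[clipped] <- 1
    data.frame(condition = spec$name,
               otc = rep(seq_len(spec$n_otc), each = spec$n_ais_per_otc),
               ais = seq_len(n), true_length = len,
               stringsAsFactors = FALSE)
  })
}

#' Generate a full condition population of rendered AIS images
#'
#' Draws true lengths from the hierarchical condition model, then renders one
#' synthetic image + ROI per AIS. Rendering parameters other than length come
#' from `gt_template`; each AIS additionally gets a uniformly drawn distance
#' to soma (3–7 µm) so traces differ realistically.
#'
#' @param spec a [condition_spec()].
#' @param seed integer seed; all draws (lengths, geometry, noise) derive from
#'   it, so the population is fully reproducible.
#' @param gt_template an [ais_ground_truth()] providing rendering defaults
#'   (its `true_length` is ignored).
#' @param render if FALSE, skip rendering and return only the manifest.
#' @return list with `objects` (list of `generate_ais_image()` results, NULL
#'   when `render = FALSE`) and `manifest` (data.frame: condition, otc, ais,
#'   true_length, true_distance_to_soma, seed).
#' @export
generate_condition_population <- function(spec, seed = 1L,
                                          gt_template = ais_ground_truth(30),
                                          render = TRUE) {
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  lens <- draw_condition_lengths(spec, seed)
  n <- nrow(lens)
  dist <- with_seed(child_seed(seed, 1L), runif(n, 3, 7))
  lens$true_distance_to_soma <- dist
  lens$seed <- vapply(seq_len(n), function(i) child_seed(seed, 10L + i), 0L)
  objects <- NULL
  if (render) {
    objects <- vector("list", n)
    for (i in seq_len(n)) {
      gt <- gt_template
      gt$true_length <- lens$true_length[i]
      gt$true_distance_to_soma <- dist[i]
      objects[[i]] <- generate_ais_image(gt, seed = lens$seed[i],
                                         id = sprintf("%s_otc%d_ais%d",
                                                      spec$name, lens$otc[i],
                                                      lens$ais[i]))
    }
  }
  list(objects = objects, manifest = lens)
}

#' Measure every AIS of a rendered population
#'
#' Runs the full measurement path (straighten, profile, threshold extent) on
#' each object of [generate_condition_population()] output and joins the
#' results to the manifest.
#'
#' @param pop output of [generate_condition_population()] with `render = TRUE`.
#' @param cfg a [morphometry_config()].
#' @return the manifest data.frame with added columns `length`,
#'   `distance_to_soma`, `qc`.
#' @export
measure_population <- function(pop, cfg = morphometry_config()) {
  if (is.null(pop$objects)) ais_error("population was not rendered", "ais_bad_input")
  res <- lapply(pop$objects, function(obj) {
    prof <- extract_profile(straighten(obj$image, obj$roi))
    tryCatch({
      m <- measure_ais(prof, cfg)
      data.frame(length = m$length, distance_to_soma = m$distance_to_soma,
                 qc = paste(m$qc_flags, collapse = ","),
                 stringsAsFactors = FALSE)
    }, ais_no_object = function(e)
      data.frame(length = NA_real_, distance_to_soma = NA_real_,
                 qc = "no_object", stringsAsFactors = FALSE))
  })
  cbind(pop$manifest, do.call(rbind, res))
}
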