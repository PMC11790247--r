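#' Printed condition statistics of the plasticity and longitudinal designs
#'
#' The per-condition mean ± SD AIS lengths (µm) of the organotypic plasticity
#' experiments (6 OTC × 50 AIS each) and of the in vivo longitudinal
#' two-photon sessions (30 AIS), used to parameterize the synthetic
#' generator when replicating those designs.
#'
#' @return a named list of [condition_spec()]s (plasticity conditions) plus
#'   `week1`/`week2` mean and SD entries for the longitudinal design.
#' @export
condition_presets <- function() {
  list(
    ctrl_20d   = condition_spec("ctrl_20d",   27.9, 3.0),
    mgso4_20d  = condition_spec("mgso4_20d",  32.1, 2.4),
    kcl_20d    = condition_spec("kcl_20d",    27.0, 2.7),
    ctrl_10d   = condition_spec("ctrl_10d",   32.1, 3.5),
    mgso4_10d  = condition_spec("mgso4_10d",  35.9, 1.2),
    kcl_10d    = condition_spec("kcl_10d",    29.9, 1.8),
    mgso4_rescue = condition_spec("mgso4_rescue", 30.6, 2.3),
    kcl_rescue   = condition_spec("kcl_rescue",   28.9, 1.9),
    longitudinal = list(week1_mean = 17.3, week1_sd = 3.9,
                        week2_mean = 16.8, week2_sd = 3.9, n = 30L,
                        within_ais_sd = 1.3),
    synpo = list(gfp_neg = 3.1, gfp_pos = 3.3),
    vgat  = list(gfp_neg = 20.7, gfp_pos = 20.8)
  )
}

#' Run the morphometry pipeline over a directory of images and ROIs
#'
#' For every TIFF in `input_dir` with a sidecar JSON and a matching
#' `<name>_roi.csv`, straightens along the ROI, extracts the normalized
#' profile and measures the AIS. Writes a tidy per-object CSV and a summary
#' JSON (group statistics, config, run log) to `out_dir`.
#'
#' @param input_dir directory of `<name>.tif` + `<name>.tif.json` +
#'   `<name>_roi.csv` triples.
#' @param out_dir output directory (created if needed).
#' @param cfg a [morphometry_config()].
#' @param channel channel label or index to measure.
#' @return the measurement data.frame, invisibly; files
#'   `measurements.csv` and `summary.json` in `out_dir`.
#' @export
run_morphometry <- function(input_dir, out_dir, cfg = morphometry_config(),
                            channel = NULL) {
  tifs <- sort(list.files(input_dir, pattern = "\\.tif$", full.names = TRUE))
  if (length(tifs) == 0L)
    ais_error(sprintf("no TIFF images found in '%s'", input_dir),
              "ais_missing_file")
  rows <- lapply(tifs, function(tf) {
    id <- sub("\\.tif$", "", basename(tf))
    roif <- file.path(input_dir, paste0(id, "_roi.csv"))
    img <- read_image_stack(tf)
    roi <- read_roi_csv(roif)
    prof <- extract_profile(straighten(img, roi))
    tryCatch({
      m <- measure_ais(prof, cfg, channel)
      data.frame(id = id, length_um = m$length,
                 distance_to_soma_um = m$distance_to_soma,
                 channel = m$channel_used,
                 qc = paste(m$qc_flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }, ais_no_object = function(e)
      data.frame(id = id, length_um = NA_real_,
                 distance_to_soma_um = NA_real_,
                 channel = NA_character_, qc = "no_object",
                 stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, rows)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  num <- res
  num$length_um <- signif(num$length_um, 6)
  num$distance_to_soma_um <- signif(num$distance_to_soma_um, 6)
  write.csv(num, file.path(out_dir, "measurements.csv"), row.names = FALSE)
  ok <- !is.na(res$length_um)
  jsonlite::write_json(
    list(n = nrow(res), n_measured = sum(ok),
         mean_length_um = signif(mean(res$length_um[ok]), 6),
         sd_length_um = signif(sd(res$length_um[ok]), 6),
         median_length_um = signif(median(res$length_um[ok]), 6),
         config = unclass(cfg),
         package_version = as.character(utils::packageVersion("aismorph"))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

measure_condition_mean <- function(spec, seed, gt_template, unit = "otc") {
  pop <- generate_condition_population(spec, seed, gt_template)
  meas <- measure_population(pop)
  if (unit == "otc") mean(tapply(meas$length, meas$otc, mean, na.rm = TRUE))
  else mean(meas$length, na.rm = TRUE)
}

#' Replicate a figure-level analysis on synthetic data
#'
#' Generates the synthetic dataset matching one of the study designs, runs
#' the corresponding pipeline and returns a report juxtaposing recovered and
#' generator-target values. Valid ids: `"fig8b"` (20-day plasticity
#' conditions), `"fig8cd"` (10-day + rescue conditions), `"fig6cd"` (STED
#' periodicity + amplitude statistic per cohort), `"fig5ab"` (synpo / vGAT
#' puncta counts), `"fig9b"` (longitudinal paired design), `"fig7"` (ephys
#' feature extraction).
#'
#' @param figure_id one of the ids above.
#' @param seed integer seed.
#' @param n_ais_per_otc AIS per culture (default 50; lower for quick runs).
#' @return a report list; contents depend on the design (always includes
#'   `figure_id`, `seed` and a `recovered` block).
#' @export
run_figure_replication <- function(figure_id, seed = 1L,
                                   n_ais_per_otc = 50L) {
  valid <- c("fig8b", "fig8cd", "fig6cd", "fig5ab", "fig9b", "fig7")
  if (!figure_id %in% valid)
    ais_error(sprintf("unknown figure_id '%s'; valid: %s", figure_id,
                      paste(valid, collapse = ", ")), "ais_bad_input")
  pre <- condition_presets()
  gt <- ais_ground_truth(30)
  if (figure_id == "fig8b") {
    specs <- pre[c("ctrl_20d", "mgso4_20d", "kcl_20d")]
    specs <- lapply(specs, function(s) { s$n_ais_per_otc <- as.integer(n_ais_per_otc); s })
    meas <- do.call(rbind, lapply(seq_along(specs), function(i)
      measure_population(generate_condition_population(
        specs[[i]], child_seed(seed, i), gt))))
    summ <- plasticity_summary(meas)
    tab <- summ$table
    return(list(figure_id = figure_id, seed = seed, summary = summ,
                recovered = list(
                  condition_means = stats::setNames(tab$mean, tab$condition),
                  mgso4_minus_ctrl = tab$mean[tab$condition == "mgso4_20d"] -
                    tab$mean[tab$condition == "ctrl_20d"]),
                target = list(condition_means = c(ctrl_20d = 27.9,
                                                  mgso4_20d = 32.1,
                                                  kcl_20d = 27.0),
                              mgso4_minus_ctrl = 4.2)))
  }
  if (figure_id == "fig8cd") {
    specs <- pre[c("ctrl_10d", "mgso4_10d", "kcl_10d",
                   "mgso4_rescue", "kcl_rescue")]
    specs <- lapply(specs, function(s) { s$n_ais_per_otc <- as.integer(n_ais_per_otc); s })
    meas <- do.call(rbind, lapply(seq_along(specs), function(i)
      measure_population(generate_condition_population(
        specs[[i]], child_seed(seed, i), gt))))
    summ <- plasticity_summary(meas)
    tab <- summ$table
    return(list(figure_id = figure_id, seed = seed, summary = summ,
                recovered = list(condition_means = stats::setNames(tab$mean,
                                                                   tab$condition)),
                target = list(condition_means = c(ctrl_10d = 32.1,
                                                  mgso4_10d = 35.9,
                                                  kcl_10d = 29.9,
                                                  mgso4_rescue = 30.6,
                                                  kcl_rescue = 28.9))))
  }
  if (figure_id == "fig6cd") {
    cohorts <- c("untreated", "dCre", "pCre")
    per_cohort <- lapply(seq_along(cohorts), function(ci) {
      acs <- lapply(1:8, function(i) {
        p <- generate_sted_profile(sted_profile_spec(noise_sd = 0.2),
                                   child_seed(seed, 10 * ci + i))
        autocorrelate(p)
      })
      avg <- average_profiles(acs)
      list(period = detect_period(avg),
           amplitude = amplitude_statistic(avg),
           amplitudes = vapply(acs, amplitude_statistic, 0))
    })
    names(per_cohort) <- cohorts
    amp <- unlist(lapply(per_cohort, `[[`, "amplitudes"))
    grp <- rep(cohorts, each = 8)
    gate <- grubbs_outliers(amp)
    keep <- amp %in% gate$retained
    cmp <- compare_groups(amp[keep], grp[keep], force_test = "anova")
    return(list(figure_id = figure_id, seed = seed,
                recovered = list(
                  periods = vapply(per_cohort, `[[`, 0, "period"),
                  amplitudes = vapply(per_cohort, `[[`, 0, "amplitude"),
                  anova_p = cmp$p_value),
                target = list(period = 190)))
  }
  if (figure_id == "fig5ab") {
    run_marker <- function(mean_count) {
      counts <- vapply(1:50, function(i) {
        s <- child_seed(seed, round(mean_count * 100) + i)
        len <- with_seed(s, runif(1, 25, 35))
        ext <- c(3, 3 + len)
        pc <- generate_puncta_channel(ext, puncta_spec(mean_count),
                                      child_seed(s, 1))
        detect_puncta(pc$channel, ext)$count
      }, 0L)
      counts
    }
    synpo <- run_marker(pre$synpo$gfp_pos)
    vgat <- run_marker(pre$vgat$gfp_pos)
    return(list(figure_id = figure_id, seed = seed,
                recovered = list(synpo_mean = mean(synpo),
                                 vgat_mean = mean(vgat)),
                target = list(synpo_mean = 3.3, vgat_mean = 20.8)))
  }
  if (figure_id == "fig9b") {
    lg <- pre$longitudinal
    res <- with_seed(seed, {
      base <- rnorm(lg$n, lg$week1_mean, sqrt(max(0, lg$week1_sd^2 -
                                                    lg$within_ais_sd^2)))
      w1 <- base + rnorm(lg$n, 0, lg$within_ais_sd)
      w2 <- base + (lg$week2_mean - lg$week1_mean) +
        rnorm(lg$n, 0, lg$within_ais_sd)
      list(w1 = pmax(w1, 2), w2 = pmax(w2, 2))
    })
    meas <- function(lens, k) vapply(seq_along(lens), function(i) {
      g <- ais_ground_truth(lens[i])
      obj <- generate_ais_image(g, child_seed(seed, 100 * k + i))
      measure_ais(extract_profile(straighten(obj$image, obj$roi)))$length
    }, 0)
    m1 <- meas(res$w1, 1)
    m2 <- meas(res$w2, 2)
    ana <- longitudinal_analysis(m1, m2)
    return(list(figure_id = figure_id, seed = seed, analysis = ana,
                recovered = list(week1_mean = mean(m1),
                                 week2_mean = mean(m2),
                                 paired_p = ana$comparison$p_value,
                                 r_squared = ana$regression$r_squared),
                target = list(week1_mean = 17.3, week2_mean = 16.8,
                              r_squared = 0.7892)))
  }
  # fig7: ephys feature recovery
  spec <- ephys_trace_spec(noise_sd = 0.2)
  sw <- generate_ephys_traces(spec, seed)
  pp <- passive_properties(sw)
  f <- first_ap_features(sw)
  fi <- fi_curve_max_slope(sw)
  rb <- rheobase(sw)
  list(figure_id = "fig7", seed = seed,
       recovered = list(rmp = pp$rmp, input_resistance = pp$input_resistance,
                        threshold = f$threshold, amplitude = f$amplitude,
                        half_width = f$half_width, max_rise = f$max_rise,
                        rheobase = as.numeric(rb),
                        fi_max_slope = fi$max_slope),
       target = list(rmp = spec$rest, input_resistance = spec$input_resistance,
                     rheobase_model = model_rheobase(spec)))
}
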