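#' Autocorrelation analysis configuration
#'
#' Parameters of the periodicity analysis of STED-scale profiles: profiles
#' are analyzed in windows of `region_length` (2 µm), and the amplitude
#' statistic compares the autocorrelation at the ring period (`target_lag`,
#' 190 nm) with the mean of the values at the flanking lags (95 and 285 nm),
#' where a periodic signal is anticorrelated.
#'
#' @param region_length analysis window, nm (default 2000).
#' @param target_lag ring-period lag, nm (default 190).
#' @param flank_lags two lags bracketing the target, nm (default 95, 285).
#' @param max_lag largest lag computed, nm (default 400; `region_length`
#'   must be at least twice this).
#' @return an object of class `autocorr_config`.
#' @export
autocorr_config <- function(region_length = 2000, target_lag = 190,
                            flank_lags = c(95, 285), max_lag = 400) {
  if (length(flank_lags) != 2L ||
      !(flank_lags[1] < target_lag && target_lag < flank_lags[2]))
    ais_error("flank_lags must bracket target_lag", "ais_bad_input")
  if (region_length < 2 * max_lag)
    ais_error("region_length must be >= 2 * max_lag", "ais_bad_input")
  structure(list(region_length = region_length, target_lag = target_lag,
                 flank_lags = flank_lags, max_lag = max_lag),
            class = "autocorr_config")
}

# Normalized autocorrelation of one window: mean-removed, divide-by-(N-k)
# estimator scaled by the divide-by-N variance, clamped to [-1, 1] so the
# estimator noise at large lags cannot push values out of range.
window_autocorr <- function(x, max_lag_samples) {
  n <- length(x)
  a <- acf(x, lag.max = max_lag_samples, type = "covariance", demean = TRUE,
           plot = FALSE)$acf[, 1, 1]
  k <- 0:max_lag_samples
  r <- (a * n / (n - k)) / a[1]
  pmin(1, pmax(-1, r))
}

#' Autocorrelation of a STED intensity profile
#'
#' Tiles the profile into non-overlapping windows of `region_length`,
#' computes the normalized (mean-removed, unbiased-lag) autocorrelation of
#' each up to `max_lag`, and averages the windows. Values at arbitrary nm
#' lags are obtained by linear interpolation between sampled lags.
#'
#' @param profile numeric intensity vector, uniformly sampled, or the output
#'   of [generate_sted_profile()].
#' @param cfg an [autocorr_config()].
#' @param spacing sample spacing in nm (taken from the profile object when
#'   one is supplied).
#' @return an `autocorrelation_profile`: list with `lags` (nm), `values`
#'   (normalized, `values[lag 0] = 1`), `spacing`, `n_regions_averaged`.
#' @export
autocorrelate <- function(profile, cfg = autocorr_config(), spacing = NULL) {
  if (is.list(profile) && !is.null(profile$intensity)) {
    spacing <- profile$spacing
    profile <- profile$intensity
  }
  if (is.null(spacing) || spacing <= 0)
    ais_error("sample spacing (nm) required", "ais_bad_input")
  n_win <- floor(cfg$region_length / spacing)
  if (length(profile) < n_win)
    ais_error(sprintf("profile shorter than region_length (%g nm)",
                      cfg$region_length), "ais_profile_too_short")
  max_lag_samples <- min(n_win - 1L, ceiling(cfg$max_lag / spacing))
  n_tiles <- floor(length(profile) / n_win)
  acs <- vapply(seq_len(n_tiles), function(i) {
    w <- profile[((i - 1L) * n_win + 1L):(i * n_win)]
    if (var(w) == 0)
      ais_error("zero-variance window: autocorrelation undefined",
                "ais_zero_variance")
    window_autocorr(w, max_lag_samples)
  }, numeric(max_lag_samples + 1L))
  vals <- rowMeans(acs)
  structure(list(lags = (0:max_lag_samples) * spacing, values = vals,
                 spacing = spacing, n_regions_averaged = n_tiles),
            class = "autocorrelation_profile")
}

#' Autocorrelation value at arbitrary lags
#'
#' Linear interpolation of an `autocorrelation_profile` at lag positions in
#' nm (sample spacing rarely hits the 95/190/285 nm lags exactly).
#'
#' @param ac an `autocorrelation_profile`.
#' @param lag_nm numeric vector of lags, nm.
#' @return autocorrelation values at `lag_nm`.
#' @export
ac_at <- function(ac, lag_nm) {
  approx(ac$lags, ac$values, xout = lag_nm, rule = 1)$y
}

#' Average autocorrelation profiles across cells
#'
#' Pointwise mean on a common lag grid (the finest spacing among the inputs,
#' up to the shortest maximum lag); `n_regions_averaged` accumulates.
#'
#' @param profiles list of `autocorrelation_profile`s.
#' @return an `autocorrelation_profile`.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0L) ais_error("no profiles to average", "ais_bad_input")
  if (!all(vapply(profiles, inherits, TRUE, "autocorrelation_profile")))
    ais_error("inputs must be autocorrelation_profiles", "ais_bad_input")
  spacing <- min(vapply(profiles, `[[`, 0, "spacing"))
  max_lag <- min(vapply(profiles, function(p) max(p$lags), 0))
  grid <- seq(0, max_lag, by = spacing)
  vals <- rowMeans(vapply(profiles, function(p) ac_at(p, grid),
                          numeric(length(grid))))
  structure(list(lags = grid, values = vals, spacing = spacing,
                 n_regions_averaged = sum(vapply(profiles, `[[`, 0,
                                                 "n_regions_averaged"))),
            class = "autocorrelation_profile")
}

#' Autocorrelation amplitude statistic
#'
#' The difference between the autocorrelation value at the ring-period lag
#' (190 nm) and the average of the values at the flanking lags (95 and
#' 285 nm): `AC(190) − (AC(95) + AC(285)) / 2`. Positive values indicate
#' periodic organization at the target period; the statistic is invariant to
#' affine transforms of the raw intensities because the autocorrelation is
#' mean-removed and variance-normalized.
#'
#' @param ac an `autocorrelation_profile`.
#' @param cfg an [autocorr_config()].
#' @return scalar amplitude statistic.
#' @export
amplitude_statistic <- function(ac, cfg = autocorr_config()) {
  ac_at(ac, cfg$target_lag) - mean(ac_at(ac, cfg$flank_lags))
}

#' Detect the dominant period of an autocorrelation profile
#'
#' The period is the lag of the first local maximum following the first local
#' minimum, refined by 3-point parabolic interpolation around the peak.
#'
#' @param ac an `autocorrelation_profile`.
#' @return period in nm. Errors with class `ais_aperiodic` when the profile
#'   has no interior local maximum after a minimum.
#' @export
detect_period <- function(ac) {
  v <- ac$values
  n <- length(v)
  if (n < 4L) ais_error("autocorrelation too short", "ais_aperiodic")
  interior <- 2:(n - 1)
  mins <- interior[v[interior] < v[interior - 1] & v[interior] <= v[interior + 1]]
  if (length(mins) == 0L)
    ais_error("aperiodic: no local minimum in the autocorrelation",
              "ais_aperiodic")
  after <- interior[interior > mins[1]]
  maxs <- after[v[after] > v[after - 1] & v[after] >= v[after + 1]]
  if (length(maxs) == 0L)
    ais_error("aperiodic: no local maximum after the first minimum",
              "ais_aperiodic")
  i <- maxs[1]
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  delta <- if (denom == 0) 0 else 0.5 * (v[i - 1] - v[i + 1]) / denom
  (ac$lags[i] + delta * ac$spacing)
}
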