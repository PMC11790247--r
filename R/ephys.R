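#' Detect action potentials in a voltage sweep
#'
#' Peaks above 0 mV whose rising phase reaches the dV/dt criterion, separated
#' by at least 1 ms (refractory). A suprathreshold excursion still rising at
#' the final sample is a truncated AP: excluded from the spike list and
#' reported via the `truncated` attribute.
#'
#' @param sweep list with `time` (ms) and `voltage` (mV), e.g. one element of
#'   a `sweep_set`.
#' @param dvdt_criterion rising-phase criterion in mV/ms (default 20).
#' @param peak_level minimum peak voltage, mV (default 0).
#' @param refractory minimum peak separation, ms (default 1).
#' @return numeric vector of spike (peak) times in ms, with attribute
#'   `truncated` (logical).
#' @export
detect_aps <- function(sweep, dvdt_criterion = 20, peak_level = 0,
                       refractory = 1) {
  t <- sweep$time; v <- sweep$voltage
  n <- length(v)
  if (n < 3L) return(structure(numeric(0), truncated = FALSE))
  dt <- t[2] - t[1]
  dvdt <- c(diff(v) / dt, 0)
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n],
               FALSE) & v > peak_level
  idx <- which(is_peak)
  # rising phase must have reached the dV/dt criterion within the last 5 ms
  back <- max(1L, round(5 / dt))
  keep <- vapply(idx, function(i) {
    lo <- max(1L, i - back)
    any(dvdt[lo:max(lo, i - 1L)] >= dvdt_criterion)
  }, TRUE)
  idx <- idx[keep]
  if (length(idx) > 1L) {  # refractory: keep the larger of close peaks
    ord <- idx[order(v[idx], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (all(abs(t[i] - t[kept]) >= refractory)) kept <- c(kept, i)
    }
    idx <- sort(kept)
  }
  truncated <- v[n] > peak_level && dvdt[n - 1L] > 0
  structure(t[idx], truncated = truncated)
}

#' Extract action-potential waveform features
#'
#' Threshold is the voltage at the first sample of the rising phase where
#' dV/dt reaches the criterion; amplitude is peak minus threshold (so
#' amplitude + threshold equals the peak voltage exactly); half-width is the
#' width at threshold + amplitude/2, with linear interpolation between
#' samples on both flanks; max rise is the largest dV/dt between threshold
#' and peak.
#'
#' @param sweep list with `time` (ms) and `voltage` (mV).
#' @param spike_time peak time of the AP to analyze, ms (from [detect_aps()]).
#' @param dvdt_criterion threshold criterion in mV/ms (default 20).
#' @return an `ap_features` list: `threshold`, `amplitude` (mV), `half_width`
#'   (ms), `max_rise` (mV/ms), `peak` (mV), `time` (ms).
#' @export
ap_features <- function(sweep, spike_time, dvdt_criterion = 20) {
  t <- sweep$time; v <- sweep$voltage
  dt <- t[2] - t[1]
  ip <- which.min(abs(t - spike_time))
  dvdt <- diff(v) / dt  # dvdt[i] = slope from sample i to i+1
  # locate the criterion-exceeding rising region just before the peak:
  # skip the low-slope zone adjacent to the peak, then walk back through the
  # fast-rising region to its onset (search limited to 10 ms before the peak)
  lo_lim <- max(1L, ip - round(10 / dt))
  j <- ip - 1L
  while (j >= lo_lim && dvdt[j] < dvdt_criterion) j <- j - 1L
  if (j < lo_lim)
    ais_error("dV/dt never reaches the criterion before the peak",
              "ais_feature_failure")
  i <- j
  while (i >= 1L && dvdt[i] >= dvdt_criterion) i <- i - 1L
  it <- i + 1L  # first sample of the rising phase at/above the criterion
  thr <- v[it]
  amp <- v[ip] - thr
  if (amp <= 0) ais_error("non-positive amplitude", "ais_feature_failure")
  half <- thr + amp / 2
  # upward crossing between it..ip
  iu <- which(v[it:ip] >= half)[1] + it - 1L
  t_up <- if (iu == it) t[it] else {
    t[iu - 1] + dt * (half - v[iu - 1]) / (v[iu] - v[iu - 1])
  }
  # downward crossing after the peak (search up to 10 ms)
  lim <- min(length(v), ip + round(10 / dt))
  below <- which(v[ip:lim] < half)
  if (length(below) == 0L)
    ais_error("no downward half crossing found", "ais_feature_failure")
  id <- below[1] + ip - 1L
  t_dn <- t[id - 1] + dt * (half - v[id - 1]) / (v[id] - v[id - 1])
  structure(list(threshold = thr, amplitude = amp,
                 half_width = t_dn - t_up,
                 max_rise = max(dvdt[it:(ip - 1L)]),
                 peak = v[ip], time = t[ip]),
            class = "ap_features")
}

# Spike times within the current step of one sweep.
step_spikes <- function(sweep, protocol, ...) {
  st <- detect_aps(sweep, ...)
  st[st >= protocol$step_onset &
       st <= protocol$step_onset + protocol$step_duration]
}

#' Rheobase of a step protocol
#'
#' Smallest injected current that elicits at least one AP during the step.
#'
#' @param sweeps a `sweep_set`.
#' @param ... passed to [detect_aps()].
#' @return current in pA, with attribute `flag`: `"ok"`,
#'   `"at_minimum_tested"` (the lowest sweep already spikes, so the true
#'   rheobase may be lower) or, when no sweep spikes, `NA` with flag
#'   `"not_reached"`.
#' @export
rheobase <- function(sweeps, ...) {
  if (!inherits(sweeps, "sweep_set")) ais_error("sweeps must be a sweep_set", "ais_bad_input")
  cur <- vapply(sweeps$sweeps, `[[`, 0, "current")
  nsp <- vapply(sweeps$sweeps, function(s)
    length(step_spikes(s, sweeps$protocol, ...)), 0L)
  firing <- which(nsp > 0L)
  if (length(firing) == 0L)
    return(structure(NA_real_, flag = "not_reached"))
  i <- firing[which.min(cur[firing])]
  structure(cur[i],
            flag = if (i == which.min(cur)) "at_minimum_tested" else "ok")
}

#' Firing-rate curve and its maximum slope
#'
#' Firing rate per sweep is the spike count during the step divided by the
#' step duration; the maximum slope f'(max) is the largest finite-difference
#' slope between consecutive current steps, in Hz/pA.
#'
#' @param sweeps a `sweep_set` with at least two sweeps.
#' @param ... passed to [detect_aps()].
#' @return list with `fi` (data.frame `current` pA, `rate` Hz) and
#'   `max_slope` (Hz/pA).
#' @export
fi_curve_max_slope <- function(sweeps, ...) {
  if (!inherits(sweeps, "sweep_set")) ais_error("sweeps must be a sweep_set", "ais_bad_input")
  if (length(sweeps$sweeps) < 2L)
    ais_error("at least two sweeps required for a slope", "ais_bad_input")
  cur <- vapply(sweeps$sweeps, `[[`, 0, "current")
  rate <- vapply(sweeps$sweeps, function(s)
    length(step_spikes(s, sweeps$protocol, ...)), 0L) /
    (sweeps$protocol$step_duration / 1000)
  slopes <- diff(rate) / diff(cur)
  list(fi = data.frame(current = cur, rate = rate),
       max_slope = if (all(rate == 0)) 0 else max(slopes))
}

#' Passive membrane properties from a step protocol
#'
#' RMP is the mean pre-step voltage across all sweeps; input resistance is
#' the steady-state deflection of the hyperpolarizing test sweep divided by
#' its current (Ohm's law; mV / pA × 1000 = MΩ). The steady state is the mean
#' over the last quarter of the step.
#'
#' @param sweeps a `sweep_set`.
#' @param test_current current of the test sweep in pA (default −100; the
#'   closest available sweep is used).
#' @return a `passive_properties` list: `rmp` (mV), `input_resistance` (MΩ),
#'   `flag` (`"ok"` or `"implausible"` for a non-positive resistance).
#' @export
passive_properties <- function(sweeps, test_current = -100) {
  if (!inherits(sweeps, "sweep_set")) ais_error("sweeps must be a sweep_set", "ais_bad_input")
  cur <- vapply(sweeps$sweeps, `[[`, 0, "current")
  neg <- which(cur < 0)
  if (length(neg) == 0L)
    ais_error("no hyperpolarizing sweep available", "ais_bad_input")
  i <- neg[which.min(abs(cur[neg] - test_current))]
  sw <- sweeps$sweeps[[i]]
  on <- sweeps$protocol$step_onset
  dur <- sweeps$protocol$step_duration
  pre <- sw$time < on
  rmp <- mean(unlist(lapply(sweeps$sweeps, function(s) s$voltage[pre])))
  ss <- sw$time >= on + 0.75 * dur & sw$time < on + dur
  deflection <- mean(sw$voltage[ss]) - rmp
  rin <- deflection / sw$current * 1000
  structure(list(rmp = rmp, input_resistance = rin,
                 flag = if (rin <= 0) "implausible" else "ok"),
            class = "passive_properties")
}

#' Waveform features of the first qualifying AP of a sweep set
#'
#' Applies the selection rule used for waveform analysis: the first AP firing
#' at least 30 ms after the start of the current injection, taken from the
#' lowest-current sweep containing such an AP. Sweeps without a qualifying
#' spike contribute no waveform features.
#'
#' @param sweeps a `sweep_set`.
#' @param min_latency minimum latency from step onset, ms (default 30).
#' @param dvdt_criterion passed to [ap_features()].
#' @return an `ap_features` list (with `current` added), or `NULL` when no
#'   sweep has a qualifying AP.
#' @export
first_ap_features <- function(sweeps, min_latency = 30, dvdt_criterion = 20) {
  cur <- vapply(sweeps$sweeps, `[[`, 0, "current")
  for (i in order(cur)) {
    st <- step_spikes(sweeps$sweeps[[i]], sweeps$protocol,
                      dvdt_criterion = dvdt_criterion)
    st <- st[st >= sweeps$protocol$step_onset + min_latency]
    if (length(st) > 0L) {
      f <- ap_features(sweeps$sweeps[[i]], st[1], dvdt_criterion)
      f$current <- cur[i]
      return(f)
    }
  }
  NULL
}
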