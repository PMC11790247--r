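#' Specification of a synthetic current-clamp step protocol
#'
#' Defines a family of current-step sweeps and the membrane model that
#' answers them: a leaky integrator (resting potential, input resistance,
#' membrane time constant) that emits a stereotyped template action
#' potential whenever the integrated voltage crosses the spike threshold.
#' Only waveform features are analyzed downstream, so a template model (not a
#' conductance-based one) is sufficient and exactly controllable.
#'
#' @param step_duration step length, ms (default 500).
#' @param step_start,step_stop,step_increment injected currents in pA
#'   (defaults −200 to +400 in 25 pA steps).
#' @param step_onset time of step onset within the sweep, ms (default 100).
#' @param post_ms recording tail after the step, ms (default 100).
#' @param sample_rate sampling rate in kHz (default 20).
#' @param rest resting membrane potential, mV.
#' @param threshold spike threshold, mV.
#' @param ap_amplitude AP amplitude above threshold, mV.
#' @param ap_halfwidth AP full width at half amplitude, ms (must span >= 10
#'   samples at `sample_rate`).
#' @param input_resistance MΩ.
#' @param tau membrane time constant, ms.
#' @param noise_sd additive Gaussian voltage noise SD, mV (default 0).
#' @return an object of class `ephys_trace_spec`.
#' @export
ephys_trace_spec <- function(step_duration = 500, step_start = -200,
                             step_stop = 400, step_increment = 25,
                             step_onset = 100, post_ms = 100,
                             sample_rate = 20,
                             rest = -65, threshold = -45, ap_amplitude = 85,
                             ap_halfwidth = 1.0, input_resistance = 150,
                             tau = 15, noise_sd = 0) {
  if (step_increment <= 0) ais_error("step_increment must be > 0", "ais_bad_input")
  if (step_stop < step_start) ais_error("step_stop must be >= step_start", "ais_bad_input")
  if (sample_rate <= 0 || ap_halfwidth * sample_rate < 10)
    ais_error("sample_rate too low: ap_halfwidth must span >= 10 samples",
              "ais_undersampled")
  if (input_resistance <= 0 || tau <= 0 || ap_amplitude <= 0)
    ais_error("input_resistance, tau and ap_amplitude must be > 0", "ais_bad_input")
  if (threshold <= rest)
    ais_error("threshold must exceed rest", "ais_bad_input")
  structure(list(step_duration = step_duration, step_start = step_start,
                 step_stop = step_stop, step_increment = step_increment,
                 step_onset = step_onset, post_ms = post_ms,
                 sample_rate = sample_rate, rest = rest,
                 threshold = threshold, ap_amplitude = ap_amplitude,
                 ap_halfwidth = ap_halfwidth,
                 input_resistance = input_resistance, tau = tau,
                 noise_sd = noise_sd),
            class = "ephys_trace_spec")
}

#' Ground-truth rheobase of the membrane model
#'
#' The smallest sustained current whose steady-state depolarization reaches
#' the spike threshold: `1000 * (threshold - rest) / input_resistance` pA.
#' Step protocols quantize upward to the next tested step.
#'
#' @param spec an [ephys_trace_spec()].
#' @return rheobase in pA.
#' @export
model_rheobase <- function(spec) {
  1000 * (spec$threshold - spec$rest) / spec$input_resistance  # pA
}

# AP template geometry. The upstroke is an exponential from threshold to
# peak over T_up = 0.35 * half-width (onset slope A*k/((e^k-1)*T_up), well
# above usual dV/dt criteria, so the waveform has the kink-like onset of
# real APs and its nominal threshold is recoverable); repolarization is a
# half-Gaussian sized so the full width at half amplitude equals the
# requested half-width.
ap_template_params <- function(ap_halfwidth, k_up = 2.5) {
  t_up <- 0.35 * ap_halfwidth
  s_half <- log(1 + (exp(k_up) - 1) / 2) / k_up
  sig_f <- (ap_halfwidth - (1 - s_half) * t_up) / sqrt(2 * log(2))
  list(k_up = k_up, t_up = t_up, sig_f = sig_f,
       duration = t_up + 4 * sig_f)
}

# Template voltage at time tau after the threshold crossing.
ap_template_voltage <- function(tau, threshold, amplitude, tp) {
  up <- tau <= tp$t_up
  v <- numeric(length(tau))
  v[up] <- threshold + amplitude *
    (exp(tp$k_up * tau[up] / tp$t_up) - 1) / (exp(tp$k_up) - 1)
  v[!up] <- threshold + amplitude *
    exp(-(tau[!up] - tp$t_up)^2 / (2 * tp$sig_f^2))
  v
}

#' Generate current-clamp sweeps from the membrane model
#'
#' Subthreshold sweeps follow the leaky-integrator charging curve exactly
#' (steady state `rest + I * Rin`, Ohm's law with pA·MΩ/1000 = mV).
#' Suprathreshold steps insert the AP template at each analytically
#' computed threshold-crossing time, then reset to rest and keep integrating,
#' so first-spike latency shrinks and spike count grows with current.
#'
#' @param spec an [ephys_trace_spec()].
#' @param seed integer seed for the noise draw.
#' @return a `sweep_set`: list with `sweeps` (list of lists `current` (pA),
#'   `time` (ms), `voltage` (mV)), `protocol` (`step_onset`,
#'   `step_duration`), `sample_rate` (kHz) and `spec`.
#' @export
generate_ephys_traces <- function(spec, seed = NULL) {
  if (!inherits(spec, "ephys_trace_spec"))
    ais_error("spec must be an ephys_trace_spec", "ais_bad_input")
  dt <- 1 / spec$sample_rate
  total <- spec$step_onset + spec$step_duration + spec$post_ms
  time <- seq(0, total, by = dt)
  currents <- seq(spec$step_start, spec$step_stop, by = spec$step_increment)
  tp <- ap_template_params(spec$ap_halfwidth)
  t_end <- spec$step_onset + spec$step_duration
  sweeps <- lapply(currents, function(I) {
    v <- rep(spec$rest, length(time))
    v_inf <- spec$rest + I * spec$input_resistance / 1000
    in_step <- time >= spec$step_onset & time < t_end
    # charging segments between spikes
    t0 <- spec$step_onset
    v0 <- spec$rest
    repeat {
      crosses <- v_inf > spec$threshold && t0 < t_end
      t_c <- if (crosses) {
        t0 + spec$tau * log((v_inf - v0) / (v_inf - spec$threshold))
      } else Inf
      seg_end <- min(t_c, t_end)
      seg <- in_step & time >= t0 & time < seg_end
      v[seg] <- v_inf + (v0 - v_inf) * exp(-(time[seg] - t0) / spec$tau)
      if (!crosses || t_c >= t_end) break
      # insert the AP template (peak at crossing + T_up), possibly truncated
      ap_idx <- which(time >= t_c & time <= t_c + tp$duration)
      v[ap_idx] <- ap_template_voltage(time[ap_idx] - t_c, spec$threshold,
                                       spec$ap_amplitude, tp)
      t0 <- t_c + tp$duration
      v0 <- spec$rest
      if (t0 >= t_end) break
    }
    # relaxation after the step from whatever value the step ended on
    v_end <- v[max(which(time < t_end))]
    post <- time >= t_end
    v[post] <- spec$rest + (v_end - spec$rest) * exp(-(time[post] - t_end) / spec$tau)
    list(current = I, time = time, voltage = v)
  })
  if (spec$noise_sd > 0) {
    sweeps <- with_seed(seed, lapply(sweeps, function(s) {
      s$voltage <- s$voltage + rnorm(length(s$voltage), 0, spec$noise_sd)
      s
    }))
  }
  structure(list(sweeps = sweeps,
                 protocol = list(step_onset = spec$step_onset,
                                 step_duration = spec$step_duration),
                 sample_rate = spec$sample_rate, spec = spec),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cur <- vapply(x$sweeps, `[[`, 0, "current")
  cat(sprintf("<sweep_set> %d sweeps, %g..%g pA, step %g ms @ %g kHz\n",
              length(cur), min(cur), max(cur), x$protocol$step_duration,
              x$sample_rate))
  invisible(x)
}
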