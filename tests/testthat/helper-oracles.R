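# Independent oracle helpers shared across tests. These deliberately
# re-derive expected values by direct enumeration / closed form, not by
# calling the package's own measurement path.

# Build a flat sweep with AP waveforms inserted at given peak times.
# Waveform written out independently of the package internals: a slow linear
# approach ramp from rest to threshold (10 mV/ms, below the detection
# criterion), an exponential upstroke (k = 2.5) over 0.35 * half_width, and
# a half-Gaussian repolarization sized so the full width at half amplitude
# equals half_width.
make_template_sweep <- function(peak_times, rest = -65, threshold = -45,
                                amplitude = 85, half_width = 1.0,
                                rate_khz = 20, total_ms = 700,
                                current = 150) {
  dt <- 1 / rate_khz
  t <- seq(0, total_ms, by = dt)
  v <- rep(rest, length(t))
  k <- 2.5
  t_up <- 0.35 * half_width
  s_half <- log(1 + (exp(k) - 1) / 2) / k
  sig_f <- (half_width - (1 - s_half) * t_up) / sqrt(2 * log(2))
  ramp <- (threshold - rest) / 10  # ms
  for (pk in peak_times) {
    tc <- pk - t_up
    in_ramp <- t >= tc - ramp & t < tc
    v[in_ramp] <- rest + 10 * (t[in_ramp] - (tc - ramp))
    up <- t >= tc & t <= pk
    v[up] <- threshold + amplitude * (exp(k * (t[up] - tc) / t_up) - 1) /
      (exp(k) - 1)
    dn <- t > pk & t <= pk + 4 * sig_f
    v[dn] <- threshold + amplitude * exp(-(t[dn] - pk)^2 / (2 * sig_f^2))
  }
  list(current = current, time = t, voltage = v)
}

# Direct-enumeration AP feature oracle: forward scan for the first sample
# where the finite-difference dV/dt reaches the criterion, then half-level
# crossings by linear interpolation. Independent of ap_features().
oracle_ap_features <- function(t, v, dvdt_criterion = 20) {
  dt <- t[2] - t[1]
  dvdt <- diff(v) / dt
  ip <- which.max(v)
  it <- which(dvdt >= dvdt_criterion)[1]
  thr <- v[it]
  amp <- v[ip] - thr
  half <- thr + amp / 2
  iu <- which(v >= half)[1]
  t_up <- t[iu - 1] + dt * (half - v[iu - 1]) / (v[iu] - v[iu - 1])
  id <- ip + which(v[(ip + 1):length(v)] < half)[1]
  t_dn <- t[id - 1] + dt * (half - v[id - 1]) / (v[id] - v[id - 1])
  list(threshold = thr, amplitude = amp, half_width = t_dn - t_up,
       max_rise = max(dvdt[it:(ip - 1)]))
}

# Exact Mann-Whitney U and two-sided p by enumeration of all group
# assignments (feasible for n <= 6 per group, no ties).
oracle_mann_whitney <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu))
  list(U = u_obs, p = p)
}

# Grubbs single-step decision from the published critical-value formula,
# written independently of grubbs_outliers().
oracle_grubbs_flags <- function(x, alpha = 0.05) {
  n <- length(x)
  G <- max(abs(x - mean(x))) / sd(x)
  tq <- qt(1 - alpha / (2 * n), n - 2)
  Gc <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  list(G = G, G_crit = Gc, reject = G > Gc)
}

# Render-and-measure shortcut used by several suites.
measure_synthetic_ais <- function(true_length, seed = 1, ...) {
  gt <- ais_ground_truth(true_length, ...)
  obj <- generate_ais_image(gt, seed = seed)
  measure_ais(extract_profile(straighten(obj$image, obj$roi)))
}
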