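test_that("AP detection finds inserted templates and skips truncated ones", {
  times <- seq(150, 450, by = 50)
  sw <- make_template_sweep(times)
  got <- detect_aps(sw)
  expect_length(got, 7L)
  expect_true(all(abs(got - times) <= 0.05 + 1e-9))
  expect_false(attr(got, "truncated"))

  flat <- make_template_sweep(numeric(0))
  expect_length(detect_aps(flat), 0L)

  # rising suprathreshold excursion cut at the sweep end
  tr <- make_template_sweep(300)
  cut <- which(tr$time <= 300)  # drop everything after the peak
  trunc <- list(current = 150, time = tr$time[cut], voltage = tr$voltage[cut])
  got2 <- detect_aps(trunc)
  expect_length(got2, 0L)
  expect_true(attr(got2, "truncated"))
})

test_that("AP features agree with the enumeration oracle on a template", {
  sw <- make_template_sweep(300)
  want <- oracle_ap_features(sw$time, sw$voltage)
  f <- ap_features(sw, 300)
  expect_equal(f$threshold, want$threshold, tolerance = 1e-9)
  expect_equal(f$amplitude, want$amplitude, tolerance = 1e-9)
  expect_equal(f$half_width, want$half_width, tolerance = 1e-9)
  expect_equal(f$max_rise, want$max_rise, tolerance = 1e-9)

  # exact identity: amplitude + threshold = peak voltage
  expect_equal(f$amplitude + f$threshold, f$peak)

  # template half-width is recovered within one sample period
  expect_lt(abs(f$half_width - 1.0), 1 / 20)
  # threshold/amplitude recovered up to onset quantization (upstroke onset
  # slope ~54 mV/ms x one 0.05 ms sample)
  expect_lt(abs(f$threshold - (-45)), 3)
  expect_lt(abs(f$amplitude - 85), 3)

  expect_error(ap_features(list(time = sw$time,
                                voltage = rep(-65, length(sw$time))), 300),
               class = "ais_feature_failure")
})

test_that("features shift correctly under a DC offset", {
  sw <- make_template_sweep(300)
  shifted <- list(current = 150, time = sw$time, voltage = sw$voltage + 5)
  f0 <- ap_features(sw, 300)
  f5 <- ap_features(shifted, 300)
  expect_equal(f5$threshold, f0$threshold + 5)
  expect_equal(f5$amplitude, f0$amplitude)
  expect_equal(f5$half_width, f0$half_width)
  expect_equal(f5$max_rise, f0$max_rise)
})

test_that("rheobase is the first step current reaching threshold", {
  spec <- ephys_trace_spec(input_resistance = 140)
  sw <- generate_ephys_traces(spec)
  cur <- seq(spec$step_start, spec$step_stop, spec$step_increment)
  want <- min(cur[cur * spec$input_resistance / 1000 >
                    spec$threshold - spec$rest])
  rb <- rheobase(sw)
  expect_equal(as.numeric(rb), want)
  expect_equal(attr(rb, "flag"), "ok")

  # monotone: raising the spike threshold never lowers rheobase
  rbs <- vapply(c(-50, -45, -40), function(th) {
    as.numeric(rheobase(generate_ephys_traces(
      ephys_trace_spec(threshold = th))))
  }, 0)
  expect_true(all(diff(rbs) >= 0))

  none <- generate_ephys_traces(ephys_trace_spec(step_stop = 100))
  rb0 <- rheobase(none)
  expect_true(is.na(rb0))
  expect_equal(attr(rb0, "flag"), "not_reached")

  low <- generate_ephys_traces(ephys_trace_spec(step_start = 200))
  expect_equal(attr(rheobase(low), "flag"), "at_minimum_tested")
})

test_that("f-I slope equals the finite-difference maximum", {
  # construct sweeps with 0,0,2,4,6 spikes in a 500 ms step at 25 pA spacing
  counts <- c(0, 0, 2, 4, 6)
  sweeps <- lapply(seq_along(counts), function(i) {
    k <- counts[i]
    make_template_sweep(if (k > 0) seq(150, 550, length.out = k) else numeric(0),
                        current = 100 + 25 * i)
  })
  ss <- structure(list(sweeps = sweeps,
                       protocol = list(step_onset = 100, step_duration = 500),
                       sample_rate = 20, spec = NULL), class = "sweep_set")
  res <- fi_curve_max_slope(ss)
  expect_equal(res$fi$rate, c(0, 0, 4, 8, 12))
  expect_equal(res$max_slope, 0.16)

  quiet <- ss
  quiet$sweeps <- lapply(quiet$sweeps, function(s) {
    s$voltage <- rep(-65, length(s$time)); s })
  expect_equal(fi_curve_max_slope(quiet)$max_slope, 0)

  single <- ss
  single$sweeps <- single$sweeps[1]
  expect_error(fi_curve_max_slope(single), class = "ais_bad_input")
})

test_that("passive properties recover the model by Ohm's law", {
  sw <- generate_ephys_traces(ephys_trace_spec())
  pp <- passive_properties(sw)
  expect_equal(pp$rmp, -65, tolerance = 1e-6)
  expect_equal(pp$input_resistance, 150, tolerance = 0.5)
  expect_equal(pp$flag, "ok")

  # noisy traces: estimate stays unbiased within 2%
  rins <- vapply(1:100, function(i) {
    passive_properties(generate_ephys_traces(
      ephys_trace_spec(noise_sd = 0.5), seed = i))$input_resistance
  }, 0)
  expect_lt(abs(mean(rins) - 150) / 150, 0.02)
})

test_that("first-AP selection enforces the 30 ms latency rule", {
  sw <- generate_ephys_traces(ephys_trace_spec())
  f <- first_ap_features(sw)
  st <- detect_aps(sw$sweeps[[which(vapply(sw$sweeps, `[[`, 0, "current") ==
                                      f$current)]])
  qualifying <- st[st >= sw$protocol$step_onset + 30]
  expect_equal(f$time, qualifying[1])

  # sweeps whose first spike is earlier than 30 ms are passed over for
  # higher-latency candidates; a spec with no qualifying AP returns NULL
  quiet <- generate_ephys_traces(ephys_trace_spec(step_stop = 0))
  expect_null(first_ap_features(quiet))
})
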