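test_that("noiseless sharp AIS renders exactly the expected pixel run", {
  # straight path: the raster can be enumerated directly, independent of the
  # measurement code; 10.5 um at 0.21 um/px is exactly 50 suprathreshold px
  gt <- ais_ground_truth(10.5, true_distance_to_soma = 5, noise_sd = 0,
                         psf_sigma = 0, edge_rise = 0, wiggle_amplitude = 0)
  obj <- generate_ais_image(gt)
  img <- obj$image$pixels[1, , ]
  axon_row <- which.max(rowSums(img))
  vals <- img[axon_row, ]
  expect_equal(sum(vals > 0.4 * max(vals)), 50L)

  # and the full measurement path sees the same run on a straight trace
  prof <- extract_profile(straighten(obj$image, obj$roi))
  expect_equal(sum(prof$normalized[1, ] > 0.4), 50L)
})

test_that("generator input validation rejects degenerate specs", {
  expect_error(ais_ground_truth(10, plateau_intensity = 10,
                                background_intensity = 10),
               class = "ais_degenerate_contrast")
  expect_error(ais_ground_truth(-5), class = "ais_bad_input")
  expect_error(sted_profile_spec(period = 190, sample_spacing = 60),
               class = "ais_undersampled")
  expect_error(ephys_trace_spec(sample_rate = 1), class = "ais_undersampled")
  expect_error(generate_ais_image(
    ais_ground_truth(10, path_control_points = data.frame(x = c(-5, 40),
                                                          y = c(10, 10)))),
    class = "ais_path_outside")
})

test_that("generators are seed-deterministic", {
  gt <- ais_ground_truth(20)
  a <- generate_ais_image(gt, seed = 99)
  b <- generate_ais_image(gt, seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_false(identical(a$image$pixels,
                         generate_ais_image(gt, seed = 100)$image$pixels))

  expect_identical(generate_sted_profile(sted_profile_spec(noise_sd = 0.2), 7),
                   generate_sted_profile(sted_profile_spec(noise_sd = 0.2), 7))
  expect_identical(generate_puncta_channel(c(3, 30), puncta_spec(5), 7),
                   generate_puncta_channel(c(3, 30), puncta_spec(5), 7))
  s <- ephys_trace_spec(noise_sd = 0.3)
  expect_identical(generate_ephys_traces(s, 7), generate_ephys_traces(s, 7))

  # population manifests regenerate identically from the same seed
  spec <- condition_spec("c", 28, 3, n_otc = 2, n_ais_per_otc = 5)
  p1 <- generate_condition_population(spec, seed = 3, render = FALSE)
  p2 <- generate_condition_population(spec, seed = 3, render = FALSE)
  expect_identical(p1$manifest, p2$manifest)
})

test_that("condition populations match their specified moments", {
  spec <- condition_spec("ctrl", 27.9, 3.0)
  lens <- draw_condition_lengths(spec, seed = 5)
  expect_equal(nrow(lens), 300L)
  expect_lt(abs(mean(lens$true_length) - 27.9), 2 * 3.0 / sqrt(300))

  # zero variance: all draws equal the mean
  flat <- draw_condition_lengths(condition_spec("f", 30, 0), seed = 1)
  expect_true(all(flat$true_length == 30))

  # large-n: sample SD converges to the specified SD
  big <- draw_condition_lengths(condition_spec("b", 30, 3, n_otc = 1,
                                               n_ais_per_otc = 10000),
                                seed = 2)
  expect_lt(abs(sd(big$true_length) - 3) / 3, 0.05)

  expect_warning(draw_condition_lengths(condition_spec("clip", 2, 3), seed = 1),
                 class = "ais_clipping")
})

test_that("manifests link every rendered object to its ground truth", {
  spec <- condition_spec("c", 28, 3, n_otc = 2, n_ais_per_otc = 4)
  pop <- generate_condition_population(spec, seed = 11)
  expect_length(pop$objects, nrow(pop$manifest))
  meas <- measure_population(pop)
  expect_false(anyNA(meas$length))
  expect_equal(meas$otc, rep(1:2, each = 4))
})

test_that("sted generator produces the constructed periodicity", {
  p <- generate_sted_profile(sted_profile_spec(modulation_depth = 1))
  peaks <- which(diff(sign(diff(p$intensity))) == -2) + 1
  expect_true(all(diff(p$positions[peaks]) == 190))

  flat <- generate_sted_profile(sted_profile_spec(modulation_depth = 0))
  expect_true(all(flat$intensity == 1))
})

test_that("puncta generator honors count model and extent", {
  fixed <- generate_puncta_channel(c(3, 30), puncta_spec(3, "fixed"), seed = 1)
  expect_equal(fixed$true_count, 3L)
  expect_equal(nrow(fixed$centers), 3L)
  expect_true(all(fixed$centers$axial_um > 3 & fixed$centers$axial_um < 30))

  empty <- generate_puncta_channel(c(3, 30), puncta_spec(0, "fixed"), seed = 1)
  expect_equal(empty$true_count, 0L)
  expect_equal(sd(empty$channel), 2, tolerance = 0.2)  # background noise only

  counts <- vapply(1:50, function(i) {
    generate_puncta_channel(c(3, 33), puncta_spec(20.8), seed = i)$true_count
  }, 0L)
  expect_lt(abs(mean(counts) - 20.8), 2 * sqrt(20.8 / 50))
})

test_that("minimum spacing is enforced between generated puncta", {
  for (i in 1:10) {
    g <- generate_puncta_channel(c(3, 33), puncta_spec(20), seed = i)
    if (g$true_count > 1) {
      d <- as.matrix(dist(g$centers))
      expect_gte(min(d[upper.tri(d)]), 0.6)
    }
  }
})

test_that("ephys traces obey Ohm's law and the spike model", {
  sw <- generate_ephys_traces(ephys_trace_spec(), seed = NULL)
  cur <- vapply(sw$sweeps, `[[`, 0, "current")
  s100 <- sw$sweeps[[which(cur == -100)]]
  late <- s100$time >= 550 & s100$time < 600  # end of the step
  expect_equal(mean(s100$voltage[late]), -65 - 15, tolerance = 0.05)

  # below model rheobase: no spikes
  rheo <- model_rheobase(sw$spec)
  sub <- sw$sweeps[[max(which(cur < rheo))]]
  expect_length(detect_aps(sub), 0L)

  # latency of the first spike decreases with current
  sup <- which(cur > rheo + 10)
  lat <- vapply(sup, function(i) {
    detect_aps(sw$sweeps[[i]])[1] - sw$protocol$step_onset
  }, 0)
  expect_true(all(diff(lat) < 0))
})
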