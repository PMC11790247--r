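prof_of <- function(v) profile_from_vector(v, 0.21, normalize = FALSE)

test_that("threshold rule picks first-above to last-above positions", {
  p <- prof_of(c(0, 0, 0.5, 1.0, 0.5, 0, 0))
  ext <- detect_extent(p)
  expect_equal(ext$start_index, 3L)  # 0-based index 2
  expect_equal(ext$end_index, 5L)    # 0-based index 4
  expect_length(ext$qc_flags, 0L)

  expect_error(detect_extent(prof_of(c(0.1, 0.4, 0.2))),
               class = "ais_no_object")

  ext2 <- detect_extent(prof_of(c(1.0, 1.0, 0.2)))
  expect_true("trace_too_short" %in% ext2$qc_flags)
})

test_that("lengths and distances follow the inclusive pixel convention", {
  m <- measure_ais(prof_of(c(0, 0, 0.5, 1.0, 0.5, 0, 0)))
  expect_equal(m$length, 3 * 0.21)          # 0.63 um
  expect_equal(m$distance_to_soma, 2 * 0.21) # 0.42 um
  expect_true("below_min_extent" %in% m$qc_flags)
})

test_that("gaps are bridged; strict mode flags fragmentation", {
  v <- c(0, 1, 1, 0.1, 1, 0)
  expect_length(detect_extent(prof_of(v))$qc_flags, 0L)
  frag <- detect_extent(prof_of(v), morphometry_config(strict_contiguity = TRUE))
  expect_true("fragmented" %in% frag$qc_flags)
  expect_equal(frag$start_index, 2L)
  expect_equal(frag$end_index, 5L)
})

test_that("noiseless sharp-edged AIS are recovered within one pixel", {
  set.seed(7)
  lens <- runif(25, 15, 40)
  errs <- vapply(seq_along(lens), function(i) {
    m <- measure_synthetic_ais(lens[i], seed = i, noise_sd = 0, psf_sigma = 0,
                               edge_rise = 0)
    m$length - lens[i]
  }, 0)
  # worst case = 1 px grid quantization plus the softening of the sharp edge
  # by bilinear resampling, which shifts each 40% crossing by up to
  # (0.5 - 0.4) px outward: 1.2 px in total
  expect_lt(max(abs(errs)), 1.2 * 0.21 + 1e-9)
  # the systematic part (mean bias) stays well under a pixel
  expect_lt(abs(mean(errs)), 0.21)
})

test_that("distance to soma is recovered within one pixel", {
  m <- measure_synthetic_ais(30, seed = 3, true_distance_to_soma = 6.3,
                             noise_sd = 0, psf_sigma = 0, edge_rise = 0)
  expect_lt(abs(m$distance_to_soma - 6.3), 0.21 + 1e-9)
})

test_that("node lengths are measured on the selectable scaffold channel", {
  m <- measure_synthetic_ais(1.5, seed = 5, true_distance_to_soma = 3,
                             noise_sd = 0, psf_sigma = 0, edge_rise = 0,
                             distal_margin = 4)
  expect_lt(abs(m$length - 1.5), 0.21 + 1e-9)

  # two channels whose extents differ by one pixel: length differs <= 1 px
  a <- c(0, 0, 1, 1, 1, 0, 0)
  b <- c(0, 0, 1, 1, 1, 1, 0)
  prof <- structure(list(positions = (0:6) * 0.21,
                         intensity = rbind(a, b),
                         normalized = rbind(a, b),
                         channel_labels = c("ankyrin-G", "Nav1.6"),
                         pixel_size = 0.21, qc_flags = character(0)),
                    class = "straightened_profile")
  n1 <- measure_node(prof)
  n2 <- measure_node(prof, channel = "Nav1.6")
  expect_equal(n1$channel_used, "ankyrin-G")
  expect_lte(abs(n1$length - n2$length), 0.21 + 1e-9)

  empty <- prof_of(rep(0, 10))
  expect_error(measure_node(empty), class = "ais_no_object")
})

test_that("raising the threshold never increases measured length", {
  set.seed(11)
  for (i in 1:10) {
    v <- pmax(0, stats::filter(c(rep(0, 5), rep(1, 30), rep(0, 5)) +
                                 rnorm(40, 0, 0.1), rep(1 / 3, 3)))
    v[is.na(v)] <- 0
    p <- prof_of(as.numeric(v / max(v)))
    lens <- vapply(c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7), function(th) {
      measure_ais(p, morphometry_config(threshold_fraction = th))$length
    }, 0)
    expect_true(all(diff(lens) <= 1e-12))
  }
})

test_that("measured length is invariant to global intensity scaling", {
  gt <- ais_ground_truth(25, noise_sd = 0)
  obj <- generate_ais_image(gt)
  m1 <- measure_ais(extract_profile(straighten(obj$image, obj$roi)))
  scaled <- obj$image
  scaled$pixels <- scaled$pixels * 37.5
  m2 <- measure_ais(extract_profile(straighten(scaled, obj$roi)))
  expect_equal(m1$length, m2$length)
  expect_equal(m1$distance_to_soma, m2$distance_to_soma)
})

test_that("erf-edge bias matches its closed form", {
  # with edge sd s and threshold q, each edge crosses threshold at
  # qnorm(q) * s outside the nominal edge, so length bias = -2*qnorm(q)*s
  w <- 0.5; q <- 0.4; s <- w / 2
  want_bias <- -2 * qnorm(q) * s
  m <- measure_synthetic_ais(30, seed = 2, noise_sd = 0, psf_sigma = 0,
                             edge_rise = w)
  expect_lt(abs((m$length - 30) - want_bias), 0.21 + 1e-9)
})

test_that("relative length time course normalizes to baseline and flags dropouts", {
  mk <- function(len) {
    gt <- ais_ground_truth(len, noise_sd = 0, psf_sigma = 0, edge_rise = 0)
    obj <- generate_ais_image(gt)
    extract_profile(straighten(obj$image, obj$roi))
  }
  constant <- lapply(rep(20, 4), mk)
  rc <- relative_length_timecourse(constant)
  expect_equal(rc$relative_length, rep(1, 4))

  shrink <- lapply(c(20, 20, 16), mk)  # 20% proximal retraction at t3
  rs <- relative_length_timecourse(shrink)
  expect_lt(abs(rs$relative_length[3] - 0.8), 0.21 / 20 + 1e-9)

  dropped <- c(constant[1:2], list(prof_of(rep(0.05, 100))), constant[3])
  rd <- relative_length_timecourse(dropped)
  expect_true(is.na(rd$relative_length[3]))
  expect_equal(rd$qc[3], "detection_failed")
})
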