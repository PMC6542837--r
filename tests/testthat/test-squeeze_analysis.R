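test_that("segmentation of the dry region behaves at the edges", {
  base <- matrix(120, 100, 100)
  # identical frame: empty mask
  expect_equal(sum(segment_squeezed_region(base, base, c(50, 50))), 0)
  # rendered dry disc of radius 30: area within 3%
  frame <- base
  frame[disc_mask(c(100, 100), c(50, 50), 30)] <- 200
  m <- segment_squeezed_region(frame, base, c(50, 50))
  expect_lt(abs(sum(m) - pi * 30^2) / (pi * 30^2), 0.03)
  # two disjoint blobs, nozzle inside the smaller: smaller wins
  frame2 <- base
  frame2[disc_mask(c(100, 100), c(25, 25), 8)] <- 200
  frame2[disc_mask(c(100, 100), c(70, 70), 20)] <- 200
  m2 <- segment_squeezed_region(frame2, base, c(25, 25))
  expect_lt(abs(sum(m2) - pi * 8^2) / (pi * 8^2), 0.10)
  expect_error(segment_squeezed_region(base, matrix(120, 50, 50),
                                       c(25, 25)), "same shape")
})

test_that("equivalent and Feret diameters match closed forms", {
  m <- disc_mask(c(250, 250), c(125, 125), 100)
  expect_equal(diameter_from_mask(m, 0.05), 10, tolerance = 0.01)
  expect_equal(diameter_from_mask(matrix(FALSE, 5, 5), 0.05), 0)
  sq <- matrix(TRUE, 100, 100)
  expect_equal(diameter_from_mask(sq, 0.1), 11.283791671,
               tolerance = 1e-9)
  expect_equal(diameter_from_mask(sq, 0.1, method = "feret"),
               sqrt(2) * 99 * 0.1, tolerance = 1e-9)
  expect_error(diameter_from_mask(sq, 0), "positive")
})

test_that("series extraction recovers synthetic trajectories frame by frame", {
  for (seed in 1:2) {
    for (regime in c("two_step_no_recovery", "oscillatory_partial_recovery",
                     "fast_rise_full_recovery")) {
      v <- make_squeeze_video(regime_spec(regime, seed))
      s <- diameter_series(v)
      truth <- v$truth$samples$diameter_mm
      tol <- pmax(2 * v$scale_mm_per_px, 0.03 * truth)
      expect_true(all(abs(s$samples$diameter_mm - truth) <= tol),
                  label = paste(regime, "seed", seed))
    }
  }
})

test_that("an all-liquid video yields the identically zero series", {
  v <- make_squeeze_video(squeeze_trajectory_spec(
    "fast_rise_full_recovery", plateau_diameter_mm = 0, seed = 4))
  s <- diameter_series(v)
  expect_true(all(s$samples$diameter_mm == 0))
})

test_that("a video without pre-jet frames is rejected", {
  v <- make_squeeze_video(squeeze_trajectory_spec(
    "fast_rise_full_recovery", plateau_diameter_mm = 4, jet_on_s = 0,
    jet_off_s = 1, seed = 1))
  expect_error(diameter_series(v), "pre-jet")
})

test_that("mean squeezed diameter averages the closed window", {
  const <- new_diameter_series(seq(0, 1.5, by = 1 / 60),
                               rep(6, length(seq(0, 1.5, by = 1 / 60))))
  expect_equal(mean_squeezed_diameter(const), 6)
  # sinusoid about 6 mm sampled on the 60 fps grid: frozen numeric oracle
  t <- seq(0, 1.5, by = 1 / 60)
  sine <- new_diameter_series(t, 6 + sin(2 * pi * 6 * t))
  expect_equal(mean_squeezed_diameter(sine), 6.09052010403,
               tolerance = 1e-9)
  expect_lt(abs(mean_squeezed_diameter(sine) - 6), 0.3)
  # ramp sampled at the window endpoints only: mean of 6.3 and 9.0
  ramp <- new_diameter_series(c(0.63, 0.9), 10 * c(0.63, 0.9))
  expect_equal(mean_squeezed_diameter(ramp), 7.65)
  early <- new_diameter_series(c(0, 0.1), c(1, 2))
  expect_error(mean_squeezed_diameter(early), "0.63")
})

test_that("residual diameter is the post-jet window mean, exactly zero on
           full recovery", {
  t <- seq(0, 1.5, by = 1 / 60)
  s5 <- new_diameter_series(t, rep(5, length(t)))
  expect_equal(residual_diameter(s5), 5)
  v <- make_squeeze_video(squeeze_trajectory_spec(
    "fast_rise_full_recovery", plateau_diameter_mm = 6, seed = 8))
  expect_identical(residual_diameter(diameter_series(v)), 0)
  # no-recovery regime keeps the plateau in the residual window
  v2 <- make_squeeze_video(regime_spec("two_step_no_recovery", 8))
  expect_lt(abs(residual_diameter(diameter_series(v2)) - 12), 0.3)
  expect_error(residual_diameter(new_diameter_series(c(0, 1), c(1, 1))),
               "1.23")
})

test_that("oscillation frequency finds the dominant periodogram peak", {
  t <- seq(0, 1.5, by = 1 / 60)
  sine <- new_diameter_series(t, 6 + sin(2 * pi * 6 * t),
                              frame_rate_hz = 60)
  f <- oscillation_frequency(sine, window = c(0, 1))
  expect_lt(abs(f - 6), 1)  # one spectral bin of the 1 s window
  const <- new_diameter_series(t, rep(6, length(t)), frame_rate_hz = 60)
  expect_true(is.na(oscillation_frequency(const, window = c(0, 1))))
  # sub-Nyquist guard for a candidate band the frame rate cannot resolve
  t8 <- seq(0, 1.5, by = 1 / 8)
  s8 <- new_diameter_series(t8, 6 + sin(2 * pi * 6 * t8),
                            frame_rate_hz = 8)
  expect_error(oscillation_frequency(s8, window = c(0, 1),
                                     candidate_band_hz = c(1, 10)),
               "Nyquist")
  expect_error(oscillation_frequency(
    new_diameter_series(c(0.1, 0.2, 0.3), c(1, 2, 1), frame_rate_hz = 10),
    window = c(0, 1)), "8 samples")
})

test_that("index errors stay within 0.3 mm across regimes and the indexes
           are stable under finer resampling", {
  wins <- analysis_windows()
  for (regime in c("two_step_no_recovery", "oscillatory_partial_recovery",
                   "fast_rise_full_recovery")) {
    spec <- regime_spec(regime, 31)
    v <- make_squeeze_video(spec)
    s <- diameter_series(v)
    truth_mean <- mean_squeezed_diameter(v$truth, wins)
    truth_res <- residual_diameter(v$truth, wins)
    expect_lt(abs(mean_squeezed_diameter(s, wins) - truth_mean), 0.3)
    expect_lt(abs(residual_diameter(s, wins) - truth_res), 0.3)
    # uniform resampling at twice the frame rate by linear interpolation
    t2 <- seq(min(s$samples$time_s), max(s$samples$time_s), by = 1 / 120)
    fine <- new_diameter_series(
      t2, stats::approx(s$samples$time_s, s$samples$diameter_mm, t2)$y,
      jet_on_s = s$jet_on_s, jet_off_s = s$jet_off_s)
    expect_lt(abs(mean_squeezed_diameter(fine, wins) -
                  mean_squeezed_diameter(s, wins)), 0.1)
    expect_lt(abs(residual_diameter(fine, wins) -
                  residual_diameter(s, wins)), 0.1)
  }
})

test_that("wettability indexes bundle both windows and the steady-phase
           frequency", {
  v <- make_squeeze_video(regime_spec("oscillatory_partial_recovery", 12))
  idx <- wettability_indexes(diameter_series(v))
  expect_equal(idx$n_frames_mean_window, 17L)
  expect_equal(idx$n_frames_residual_window, 17L)
  expect_lt(abs(idx$mean_squeezed_diameter_mm - 6.8), 0.4)
  expect_lt(abs(idx$residual_diameter_mm - 5), 0.4)
  expect_false(is.na(idx$oscillation_freq_hz))
  v2 <- make_squeeze_video(regime_spec("fast_rise_full_recovery", 12))
  idx2 <- wettability_indexes(diameter_series(v2))
  expect_true(is.na(idx2$oscillation_freq_hz))
  expect_identical(idx2$residual_diameter_mm, 0)
})
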