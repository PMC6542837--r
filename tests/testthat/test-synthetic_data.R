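test_that("stained-dish encoding inverts the decompensation transform", {
  # zero density encodes to full-scale white inside the dish
  sp0 <- stain_phantom_spec(c(30, 30), c(15.5, 15.5), 10,
                            matrix(0, 30, 30), noise_sd = 0)
  ph0 <- make_stained_dish_image(sp0)
  expect_true(all(ph0$image$intensity == 255))
  # a uniform I' field of gamma encodes to one decade below white
  sp1 <- stain_phantom_spec(c(30, 30), c(15.5, 15.5), 10,
                            matrix(1.8, 30, 30), gamma = 1.8, noise_sd = 0)
  ph1 <- make_stained_dish_image(sp1)
  expect_true(all(ph1$image$intensity[ph1$dish_mask] == 26))
})

test_that("noise-free encode/decode round trip stays within the count
           quantization bound at every pixel", {
  dim <- c(50, 50)
  field <- with(list(), {
    set.seed(5)
    matrix(runif(prod(dim), 0, 2.5), dim[1], dim[2])
  })
  sp <- stain_phantom_spec(dim, c(25.5, 25.5), 20, field, gamma = 1.8,
                           noise_sd = 0, seed = 5)
  ph <- make_stained_dish_image(sp)
  od <- decompensate(ph$image, 1.8)
  # rounding I by <= 0.5 counts propagates to (gamma/ln10)*|ln(I_r/I_t)|
  counts <- ph$image$intensity
  bound <- (1.8 / log(10)) * log(counts / pmax(counts - 0.5, 0.5))
  err <- abs(od$i_prime - ph$true_i_prime)
  expect_true(all(err <= bound + 1e-12))
})

test_that("densities that would round below one count are rejected", {
  expect_error(
    make_stained_dish_image(
      stain_phantom_spec(c(20, 20), c(10.5, 10.5), 7,
                         matrix(6, 20, 20), gamma = 1.8)),
    "round below 1 count")
})

test_that("phantom generation is deterministic in the seed", {
  sp <- function(s) stain_phantom_spec(c(30, 30), c(15.5, 15.5), 10,
                                       matrix(0.8, 30, 30), noise_sd = 3,
                                       seed = s)
  expect_identical(make_stained_dish_image(sp(9))$image$intensity,
                   make_stained_dish_image(sp(9))$image$intensity)
  expect_false(identical(make_stained_dish_image(sp(9))$image$intensity,
                         make_stained_dish_image(sp(10))$image$intensity))
  vs <- squeeze_trajectory_spec("fast_rise_full_recovery",
                                plateau_diameter_mm = 4, seed = 3)
  expect_identical(make_squeeze_video(vs)$frames,
                   make_squeeze_video(vs)$frames)
  bs <- bubble_phantom_spec(110, 40, 20, noise_sd = 8, seed = 4)
  expect_identical(make_bubble_image(bs)$image$intensity,
                   make_bubble_image(bs)$image$intensity)
})

test_that("trajectory templates respect the regime semantics", {
  # fast rise + full recovery: 0 before onset, plateau mid-jet, 0 after
  sp <- squeeze_trajectory_spec("fast_rise_full_recovery",
                                plateau_diameter_mm = 6, rise_time_s = 0.1,
                                recovery_time_s = 0.1, jet_on_s = 0,
                                jet_off_s = 1)
  expect_equal(squeeze_trajectory(sp, c(-0.2, -0.01)), c(0, 0))
  expect_equal(squeeze_trajectory(sp, c(0.1, 0.5, 1.0)), c(6, 6, 6))
  expect_equal(squeeze_trajectory(sp, c(1.11, 1.5)), c(0, 0))
  # two-step: shoulder at 5 mm until 0.2 s, then spread, never recovers
  sp2 <- squeeze_trajectory_spec("two_step_no_recovery",
                                 plateau_diameter_mm = 17,
                                 first_step_diameter_mm = 5,
                                 rise_time_s = 0.05, step_time_s = 0.2,
                                 spread_ramp_s = 0.2, jet_on_s = 0,
                                 jet_off_s = 1)
  expect_equal(squeeze_trajectory(sp2, c(0.1, 0.2)), c(5, 5))
  expect_equal(squeeze_trajectory(sp2, c(0.5, 1.0, 1.5)), c(17, 17, 17))
  # oscillatory: sinusoid about the plateau during the jet, decays to the
  # residual afterwards
  sp3 <- squeeze_trajectory_spec("oscillatory_partial_recovery",
                                 plateau_diameter_mm = 6, osc_freq_hz = 6,
                                 osc_amplitude_mm = 1,
                                 residual_diameter_mm = 5,
                                 rise_time_s = 0.1, jet_on_s = 0,
                                 jet_off_s = 1)
  tt <- seq(0.15, 0.95, by = 0.005)
  d <- squeeze_trajectory(sp3, tt)
  expect_equal(mean(d), 6, tolerance = 0.05)
  expect_equal(max(d), 7, tolerance = 0.02)
  expect_equal(squeeze_trajectory(sp3, 1.4), 5)
})

test_that("trajectory spec validation enforces the physical invariants", {
  expect_error(squeeze_trajectory_spec("fast_rise_full_recovery",
                                       plateau_diameter_mm = 6,
                                       jet_on_s = 1, jet_off_s = 0.5),
               "jet_on")
  expect_error(squeeze_trajectory_spec("oscillatory_partial_recovery",
                                       plateau_diameter_mm = 6,
                                       osc_freq_hz = 6, frame_rate_hz = 8),
               "Nyquist")
  expect_error(squeeze_trajectory_spec("fast_rise_full_recovery",
                                       plateau_diameter_mm = 6,
                                       residual_diameter_mm = 2),
               "residual")
  expect_error(squeeze_trajectory_spec("fast_rise_full_recovery",
                                       plateau_diameter_mm = -1),
               ">= 0")
})

test_that("rendered videos carry a consistent ground truth", {
  sp <- squeeze_trajectory_spec("fast_rise_full_recovery",
                                plateau_diameter_mm = 5, seed = 21)
  v <- make_squeeze_video(sp)
  expect_equal(length(v$frames), length(v$truth$samples$time_s))
  # re-measuring a mid-jet frame agrees with the stored trajectory
  i <- which.min(abs(v$times_s - 0.6))
  baseline <- v$frames[[1]]
  m <- segment_squeezed_region(v$frames[[i]], baseline, v$nozzle_axis)
  d <- diameter_from_mask(m, v$scale_mm_per_px)
  expect_lt(abs(d - v$truth$samples$diameter_mm[i]),
            2 * v$scale_mm_per_px)
  # degenerate plateau: all-liquid frames, identically zero truth
  sp0 <- squeeze_trajectory_spec("fast_rise_full_recovery",
                                 plateau_diameter_mm = 0, seed = 1)
  v0 <- make_squeeze_video(sp0)
  expect_true(all(v0$truth$samples$diameter_mm == 0))
  # field-of-view guard
  expect_error(make_squeeze_video(sp, image_dim = c(40, 40)),
               "field of view")
})

test_that("video write/read round trip preserves frames, manifest and truth", {
  sp <- squeeze_trajectory_spec("fast_rise_full_recovery",
                                plateau_diameter_mm = 3, seed = 2)
  v <- make_squeeze_video(sp)
  dir <- file.path(tempdir(), "rt_video")
  write_squeeze_video(v, dir, experiment_id = "e1", condition = "demo")
  v2 <- read_squeeze_video(dir)
  expect_identical(v2$frames, v$frames)
  expect_equal(v2$frame_rate_hz, v$frame_rate_hz)
  expect_equal(v2$jet_on_s, v$jet_on_s)
  expect_equal(v2$truth$samples$diameter_mm, v$truth$samples$diameter_mm)
  expect_equal(v2$condition, "demo")
  unlink(dir, recursive = TRUE)
})

test_that("bubble phantoms store the analytic cap angle", {
  expect_equal(make_bubble_image(bubble_phantom_spec(90))$true_angle_deg, 90)
  # centre offset by r/2 into the bubble: 90 + asin(1/2) = 120
  sp <- bubble_phantom_spec(120, bubble_radius_px = 60, baseline_row = 30)
  expect_equal(sp$center[1] - sp$baseline_row, 30, tolerance = 1e-9)
  # symmetric offset toward the liquid: 60
  sp2 <- bubble_phantom_spec(60, bubble_radius_px = 60, baseline_row = 40)
  expect_equal(sp2$center[1] - sp2$baseline_row, -30, tolerance = 1e-9)
  expect_error(bubble_phantom_spec(5), "contact_angle_deg")
  expect_error(bubble_phantom_spec(175), "contact_angle_deg")
})
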