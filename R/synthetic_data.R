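#' Specification of a synthetic stained-dish phantom
#'
#' Describes a gamma-encoded scanner image of a crystal-violet-stained dish
#' with a known stain-density field, used to test the quantification chain
#' end to end. The density field is expressed on the decompensated-brightness
#' scale through an optional linear calibration `d = c1 I' + c0` (identity by
#' default, so OD and I' coincide).
#'
#' @param image_dim integer length-2, image (rows, cols).
#' @param dish_center numeric length-2 (row, col) of the dish centre, px.
#' @param dish_radius_px dish-bottom radius in pixels; the dish must fit
#'   inside the frame.
#' @param true_od_field scalar or matrix of size `image_dim`: stain density
#'   (OD units, >= 0) at each pixel; values outside the dish are ignored and
#'   rendered as clean substrate.
#' @param gamma display gamma used for encoding (> 0).
#' @param bit_depth 8 or 16.
#' @param noise_sd additive Gaussian intensity noise, counts.
#' @param seed integer seed; all randomness in the phantom derives from it.
#' @param c0,c1 calibration mapping density to brightness (`I' = (d-c0)/c1`).
#' @return a `stain_phantom_spec`.
#' @export
stain_phantom_spec <- function(image_dim, dish_center, dish_radius_px,
                               true_od_field, gamma = 1.8, bit_depth = 8L,
                               noise_sd = 0, seed = 1L, c0 = 0, c1 = 1) {
  if (gamma <= 0) stop("`gamma` must be positive", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16",
                                       call. = FALSE)
  if (is.matrix(true_od_field)) {
    if (!all(dim(true_od_field) == image_dim))
      stop("`true_od_field` matrix must match `image_dim`", call. = FALSE)
  } else {
    true_od_field <- matrix(true_od_field, image_dim[1], image_dim[2])
  }
  if (any(true_od_field < 0))
    stop("`true_od_field` must be non-negative everywhere", call. = FALSE)
  if (dish_center[1] - dish_radius_px < 1 ||
      dish_center[1] + dish_radius_px > image_dim[1] ||
      dish_center[2] - dish_radius_px < 1 ||
      dish_center[2] + dish_radius_px > image_dim[2])
    stop("dish does not fit inside the image frame", call. = FALSE)
  if (c1 == 0) stop("`c1` must be nonzero", call. = FALSE)
  structure(
    list(image_dim = as.integer(image_dim), dish_center = dish_center,
         dish_radius_px = dish_radius_px, true_od_field = true_od_field,
         gamma = gamma, bit_depth = as.integer(bit_depth),
         noise_sd = noise_sd, seed = as.integer(seed), c0 = c0, c1 = c1),
    class = "stain_phantom_spec")
}

#' Render a stained-dish phantom image
#'
#' Encodes the phantom's density field into gamma-compensated counts by
#' inverting the decompensation transform: `I = (2^b - 1) * 10^(-I'/gamma)`,
#' rounding to integer counts and optionally adding clipped Gaussian noise.
#' Pixels outside the dish are rendered at full-scale white (clean
#' substrate, `I' = 0`).
#'
#' @param spec a [stain_phantom_spec()].
#' @return list with `image` (a [gray_image()]), `true_i_prime` (matrix, the
#'   noise-free decompensated-brightness field actually encoded),
#'   `true_od` (the density field), `dish_mask`, and the `spec`.
#' @export
make_stained_dish_image <- function(spec) {
  stopifnot(inherits(spec, "stain_phantom_spec"))
  full <- 2^spec$bit_depth - 1
  dish <- dist2_grid(spec$image_dim[1], spec$image_dim[2],
                     spec$dish_center) <= spec$dish_radius_px^2
  i_prime <- (spec$true_od_field - spec$c0) / spec$c1
  if (any(i_prime[dish] < 0))
    stop("density field maps to negative I' under the calibration",
         call. = FALSE)
  i_prime[!dish] <- 0
  counts_exact <- full * 10^(-i_prime / spec$gamma)
  if (any(counts_exact < 0.5))
    stop("density too high for the bit depth: encoded intensity would ",
         "round below 1 count (the log transform diverges at 0)",
         call. = FALSE)
  counts <- round(counts_exact)
  if (spec$noise_sd > 0) {
    counts <- with_seed(spec$seed, {
      n <- counts + stats::rnorm(length(counts), sd = spec$noise_sd)
      round(pmin(pmax(n, 0), full))
    })
    dim(counts) <- spec$image_dim
  }
  list(image = gray_image(counts, bit_depth = spec$bit_depth),
       true_i_prime = i_prime, true_od = spec$true_od_field,
       dish_mask = dish, spec = spec)
}

#' Smoothed random stain field with an exact target coverage
#'
#' Builds a bimodal density field by thresholding a smoothed Gaussian random
#' field at the empirical quantile that puts the requested fraction of
#' centre-half-radius ROI pixels in the stained class, so the ground-truth
#' coverage is known to a pixel quantum. Emulates the patchy appearance of a
#' partly colonised dish.
#'
#' @param image_dim,dish_center,dish_radius_px dish geometry, as in
#'   [stain_phantom_spec()].
#' @param coverage target stained fraction of the analysis ROI, in `[0, 1]`.
#' @param od_background,od_stained the two density levels (OD units).
#' @param smoothness_px Gaussian blur sigma shaping the patch size.
#' @param seed integer seed.
#' @return list with `field` (density matrix), `stained_mask`, `roi_mask`
#'   (centre-half-radius disc) and `true_coverage_pct` measured on the ROI.
#' @export
make_coverage_field <- function(image_dim, dish_center, dish_radius_px,
                                coverage, od_background = 0.1,
                                od_stained = 1.0, smoothness_px = 6,
                                seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, od_stained > od_background)
  roi <- dist2_grid(image_dim[1], image_dim[2], dish_center) <=
    (dish_radius_px / 2)^2
  z <- with_seed(seed, matrix(stats::rnorm(prod(image_dim)),
                              image_dim[1], image_dim[2]))
  z <- as.matrix(EBImage::gblur(z, sigma = smoothness_px))
  stained <- matrix(FALSE, image_dim[1], image_dim[2])
  if (coverage > 0) {
    cut <- stats::quantile(z[roi], 1 - coverage, type = 1)
    stained <- z >= cut
  }
  field <- matrix(od_background, image_dim[1], image_dim[2])
  field[stained] <- od_stained
  list(field = field, stained_mask = stained, roi_mask = roi,
       true_coverage_pct = 100 * sum(stained & roi) / sum(roi))
}

#' Specification of a synthetic liquid-squeezing trajectory
#'
#' Phenomenological diameter-versus-time templates for the three behaviours
#' seen when an air-jet squeezes the liquid film off a submerged dish
#' bottom:
#' \describe{
#'   \item{`two_step_no_recovery`}{hydrophobic bare substrate: the dry spot
#'     opens to a first shoulder (default 5 mm, held until 0.2 s) and then
#'     spreads to a wide plateau; the liquid never recovers after the jet.}
#'   \item{`oscillatory_partial_recovery`}{hydrophilic substrate: the dry
#'     spot oscillates (default 6 Hz) about a moderate mean diameter and
#'     only partly recovers, leaving a residual dry area.}
#'   \item{`fast_rise_full_recovery`}{biofilm-covered substrate: fast rise
#'     to a constant diameter and complete rewetting within the recovery
#'     time (default 0.1 s) after the jet stops.}
#' }
#'
#' @param regime one of the three template names.
#' @param plateau_diameter_mm main (or mean, for the oscillatory regime)
#'   dry-spot diameter during the jet, mm.
#' @param first_step_diameter_mm two-step regime: the first shoulder, mm.
#' @param step_time_s two-step regime: time the first shoulder is held, s.
#' @param spread_ramp_s two-step regime: ramp duration from shoulder to
#'   plateau, s.
#' @param osc_freq_hz,osc_amplitude_mm oscillatory regime parameters.
#' @param rise_time_s initial opening ramp duration, s.
#' @param recovery_time_s rewetting ramp duration after the jet stops, s.
#' @param residual_diameter_mm diameter left after recovery, mm; must be 0
#'   for the full-recovery regime.
#' @param jet_on_s,jet_off_s air-jet interval in video time, s.
#' @param frame_rate_hz camera frame rate; must exceed twice the oscillation
#'   frequency for the oscillatory regime.
#' @param scale_mm_per_px camera spatial scale.
#' @param noise_sd pixel noise when rendered, counts.
#' @param seed integer seed for rendering noise.
#' @return a `squeeze_trajectory_spec`.
#' @export
squeeze_trajectory_spec <- function(
    regime = c("two_step_no_recovery", "oscillatory_partial_recovery",
               "fast_rise_full_recovery"),
    plateau_diameter_mm, first_step_diameter_mm = 5, step_time_s = 0.2,
    spread_ramp_s = 0.2, osc_freq_hz = 6, osc_amplitude_mm = 1,
    rise_time_s = 0.1, recovery_time_s = 0.1, residual_diameter_mm = NULL,
    jet_on_s = 0.1, jet_off_s = 1.1, frame_rate_hz = 60,
    scale_mm_per_px = 0.05, noise_sd = 3, seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(residual_diameter_mm))
    residual_diameter_mm <- switch(regime,
      two_step_no_recovery = plateau_diameter_mm,
      oscillatory_partial_recovery = 0.75 * plateau_diameter_mm,
      fast_rise_full_recovery = 0)
  if (jet_on_s >= jet_off_s)
    stop("`jet_on_s` must precede `jet_off_s`", call. = FALSE)
  lens <- c(plateau_diameter_mm, first_step_diameter_mm, osc_amplitude_mm,
            residual_diameter_mm, rise_time_s, recovery_time_s,
            scale_mm_per_px)
  if (any(lens < 0)) stop("lengths and durations must be >= 0", call. = FALSE)
  if (regime == "oscillatory_partial_recovery" &&
      frame_rate_hz <= 2 * osc_freq_hz)
    stop("frame rate must exceed twice the oscillation frequency ",
         "(Nyquist)", call. = FALSE)
  if (regime == "fast_rise_full_recovery" && residual_diameter_mm != 0)
    stop("full-recovery regime requires residual_diameter_mm = 0",
         call. = FALSE)
  structure(
    list(regime = regime, plateau_diameter_mm = plateau_diameter_mm,
         first_step_diameter_mm = first_step_diameter_mm,
         step_time_s = step_time_s, spread_ramp_s = spread_ramp_s,
         osc_freq_hz = osc_freq_hz, osc_amplitude_mm = osc_amplitude_mm,
         rise_time_s = rise_time_s, recovery_time_s = recovery_time_s,
         residual_diameter_mm = residual_diameter_mm, jet_on_s = jet_on_s,
         jet_off_s = jet_off_s, frame_rate_hz = frame_rate_hz,
         scale_mm_per_px = scale_mm_per_px, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "squeeze_trajectory_spec")
}

# linear ramp helper: value moving a -> b over [t0, t0 + dur], clamped
ramp <- function(t, t0, dur, a, b) {
  if (dur <= 0) return(ifelse(t < t0, a, b))
  frac <- pmin(pmax((t - t0) / dur, 0), 1)
  a + (b - a) * frac
}

#' Ground-truth squeezed diameter at given times
#'
#' Evaluates the trajectory template of a [squeeze_trajectory_spec()] at
#' absolute video times (seconds). Deterministic; noise only enters when the
#' trajectory is rendered to frames.
#'
#' @param spec a `squeeze_trajectory_spec`.
#' @param times_s numeric vector of video times.
#' @return numeric vector of diameters, mm.
#' @export
squeeze_trajectory <- function(spec, times_s) {
  stopifnot(inherits(spec, "squeeze_trajectory_spec"))
  tr <- times_s - spec$jet_on_s          # time since jet onset
  jet_dur <- spec$jet_off_s - spec$jet_on_s
  d <- numeric(length(tr))
  on <- tr >= 0
  switch(spec$regime,
    two_step_no_recovery = {
      d[on] <- ramp(tr[on], 0, spec$rise_time_s, 0,
                    spec$first_step_diameter_mm)
      late <- on & tr >= spec$step_time_s
      d[late] <- ramp(tr[late], spec$step_time_s, spec$spread_ramp_s,
                      spec$first_step_diameter_mm, spec$plateau_diameter_mm)
      # no recovery: plateau persists after jet off
    },
    oscillatory_partial_recovery = {
      d[on] <- ramp(tr[on], 0, spec$rise_time_s, 0, spec$plateau_diameter_mm)
      osc <- on & tr >= spec$rise_time_s & tr <= jet_dur
      d[osc] <- spec$plateau_diameter_mm + spec$osc_amplitude_mm *
        sin(2 * pi * spec$osc_freq_hz * (tr[osc] - spec$rise_time_s))
      off <- tr > jet_dur
      d_off <- spec$plateau_diameter_mm + spec$osc_amplitude_mm *
        sin(2 * pi * spec$osc_freq_hz * (jet_dur - spec$rise_time_s))
      d[off] <- ramp(tr[off], jet_dur, spec$recovery_time_s, d_off,
                     spec$residual_diameter_mm)
    },
    fast_rise_full_recovery = {
      d[on] <- ramp(tr[on], 0, spec$rise_time_s, 0, spec$plateau_diameter_mm)
      off <- tr > jet_dur
      d[off] <- ramp(tr[off], jet_dur, spec$recovery_time_s,
                     spec$plateau_diameter_mm, 0)
    })
  pmax(d, 0)
}

#' Render a synthetic liquid-squeezing video
#'
#' Renders each frame as a liquid background with a brighter dry circular
#' region under the nozzle whose equivalent diameter follows the
#' ground-truth trajectory, plus clipped Gaussian pixel noise. The frame is
#' auto-sized to hold the largest diameter the template can reach unless an
#' `image_dim` is given.
#'
#' @param spec a [squeeze_trajectory_spec()].
#' @param duration_s total video duration from time 0; default covers the
#'   jet plus 0.5 s of aftermath.
#' @param image_dim optional (rows, cols); a diameter exceeding the field of
#'   view is an error.
#' @param liquid_level,contrast liquid intensity and dry-minus-liquid
#'   contrast step, counts (8-bit).
#' @return a `squeeze_video`: list with `frames` (list of count matrices),
#'   `times_s`, `truth` (a [diameter_series] of the ground truth),
#'   `nozzle_axis`, and acquisition metadata.
#' @export
make_squeeze_video <- function(spec, duration_s = NULL, image_dim = NULL,
                               liquid_level = 120, contrast = 80) {
  stopifnot(inherits(spec, "squeeze_trajectory_spec"))
  if (is.null(duration_s)) duration_s <- spec$jet_off_s + 0.5
  n_frames <- floor(duration_s * spec$frame_rate_hz) + 1L
  times <- (seq_len(n_frames) - 1L) / spec$frame_rate_hz
  d_mm <- squeeze_trajectory(spec, times)
  max_possible <- max(spec$plateau_diameter_mm + spec$osc_amplitude_mm *
                        (spec$regime == "oscillatory_partial_recovery"),
                      spec$first_step_diameter_mm *
                        (spec$regime == "two_step_no_recovery"),
                      spec$residual_diameter_mm)
  need_px <- ceiling(max_possible / spec$scale_mm_per_px) + 12L
  if (is.null(image_dim)) image_dim <- c(need_px, need_px)
  if (max(d_mm) / spec$scale_mm_per_px > min(image_dim) - 4)
    stop("squeezed diameter exceeds the field of view", call. = FALSE)
  nozzle <- (image_dim + 1) / 2
  d2 <- dist2_grid(image_dim[1], image_dim[2], nozzle)
  r_px <- d_mm / (2 * spec$scale_mm_per_px)
  frames <- with_seed(spec$seed, lapply(seq_len(n_frames), function(i) {
    f <- matrix(liquid_level, image_dim[1], image_dim[2])
    if (r_px[i] > 0) f[d2 <= r_px[i]^2] <- liquid_level + contrast
    if (spec$noise_sd > 0)
      f <- f + stats::rnorm(length(f), sd = spec$noise_sd)
    m <- round(pmin(pmax(f, 0), 255))
    dim(m) <- image_dim
    m
  }))
  truth <- new_diameter_series(
    time_s = times - spec$jet_on_s, diameter_mm = d_mm,
    jet_on_s = 0, jet_off_s = spec$jet_off_s - spec$jet_on_s,
    scale_mm_per_px = spec$scale_mm_per_px,
    frame_rate_hz = spec$frame_rate_hz)
  structure(
    list(frames = frames, times_s = times, truth = truth,
         nozzle_axis = nozzle, frame_rate_hz = spec$frame_rate_hz,
         scale_mm_per_px = spec$scale_mm_per_px, jet_on_s = spec$jet_on_s,
         jet_off_s = spec$jet_off_s, bit_depth = 8L, spec = spec),
    class = "squeeze_video")
}

#' Write a squeeze video as numbered PNG frames plus a YAML manifest
#'
#' Writes `frame_0001.png`, ..., a `manifest.yaml` (frame rate, spatial
#' scale, jet timestamps, bit depth, nozzle position) and the ground truth
#' as `truth.csv` (`time_s`, `diameter_mm`).
#'
#' @param video a `squeeze_video`.
#' @param dir output directory (created if needed).
#' @param experiment_id,condition optional labels stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_squeeze_video <- function(video, dir, experiment_id = NULL,
                                condition = NULL) {
  stopifnot(inherits(video, "squeeze_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames))
    png::writePNG(video$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%04d.png", i)))
  manifest <- list(
    frame_rate_hz = video$frame_rate_hz,
    scale_mm_per_px = video$scale_mm_per_px,
    jet_on_s = video$jet_on_s, jet_off_s = video$jet_off_s,
    bit_depth = video$bit_depth,
    nozzle_row = video$nozzle_axis[1], nozzle_col = video$nozzle_axis[2])
  if (!is.null(experiment_id)) manifest$experiment_id <- experiment_id
  if (!is.null(condition)) manifest$condition <- condition
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  utils::write.csv(video$truth$samples, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a squeeze video written by [write_squeeze_video()]
#'
#' @param dir directory holding numbered PNG frames and `manifest.yaml`.
#' @return a `squeeze_video` (without ground truth unless `truth.csv` is
#'   present).
#' @export
read_squeeze_video <- function(dir) {
  mpath <- file.path(dir, "manifest.yaml")
  if (!file.exists(mpath))
    stop("manifest.yaml not found in ", dir, call. = FALSE)
  m <- yaml::read_yaml(mpath)
  for (f in c("frame_rate_hz", "scale_mm_per_px", "jet_on_s", "jet_off_s"))
    if (is.null(m[[f]]))
      stop("manifest is missing required field `", f, "`", call. = FALSE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no frames found in ", dir, call. = FALSE)
  frames <- lapply(files, function(p) round(rgb_to_gray(png::readPNG(p)) * 255))
  times <- (seq_along(frames) - 1L) / m$frame_rate_hz
  truth <- NULL
  tpath <- file.path(dir, "truth.csv")
  if (file.exists(tpath)) {
    tt <- utils::read.csv(tpath)
    truth <- new_diameter_series(tt$time_s, tt$diameter_mm,
                                 jet_on_s = 0,
                                 jet_off_s = m$jet_off_s - m$jet_on_s,
                                 scale_mm_per_px = m$scale_mm_per_px,
                                 frame_rate_hz = m$frame_rate_hz)
  }
  nozzle <- if (!is.null(m$nozzle_row)) c(m$nozzle_row, m$nozzle_col)
            else (dim(frames[[1]]) + 1) / 2
  structure(
    list(frames = frames, times_s = times, truth = truth,
         nozzle_axis = nozzle, frame_rate_hz = m$frame_rate_hz,
         scale_mm_per_px = m$scale_mm_per_px, jet_on_s = m$jet_on_s,
         jet_off_s = m$jet_off_s,
         bit_depth = if (is.null(m$bit_depth)) 8L else m$bit_depth,
         experiment_id = m$experiment_id, condition = m$condition),
    class = "squeeze_video")
}

#' Specification of a synthetic captive-bubble image
#'
#' A captive bubble pressed against a downward-facing submerged surface is
#' modelled as a circular cap cut by the baseline row of the solid. The
#' stored ground truth is the analytic bubble-side contact angle: for a
#' circle of radius `r` whose centre sits a signed distance `h` beyond the
#' baseline into the bubble phase, the angle between baseline and tangent at
#' the contact point, measured through the bubble, is `90 + asin(h/r)`
#' degrees.
#'
#' @param contact_angle_deg ground-truth bubble-side angle, in `[10, 170]`.
#' @param bubble_radius_px circle radius in pixels.
#' @param baseline_row pixel row of the solid surface; bubble lies below it
#'   (larger row indices).
#' @param image_dim (rows, cols); bubble must fit entirely in frame.
#' @param noise_sd additive intensity noise, counts (8-bit).
#' @param seed integer seed.
#' @return a `bubble_phantom_spec`.
#' @export
bubble_phantom_spec <- function(contact_angle_deg, bubble_radius_px = 60,
                                baseline_row = 30, image_dim = NULL,
                                noise_sd = 0, seed = 1L) {
  if (contact_angle_deg < 10 || contact_angle_deg > 170)
    stop("`contact_angle_deg` must lie in [10, 170]", call. = FALSE)
  h <- bubble_radius_px * sin((contact_angle_deg - 90) * pi / 180)
  if (is.null(image_dim)) {
    depth <- baseline_row + ceiling(h + bubble_radius_px) + 15
    width <- 2 * ceiling(bubble_radius_px) + 30
    image_dim <- c(depth, width)
  }
  center <- c(baseline_row + h, (image_dim[2] + 1) / 2)
  if (center[1] + bubble_radius_px > image_dim[1] - 1 ||
      center[2] - bubble_radius_px < 2 ||
      center[2] + bubble_radius_px > image_dim[2] - 1)
    stop("bubble does not fit entirely within the frame", call. = FALSE)
  structure(
    list(contact_angle_deg = contact_angle_deg,
         bubble_radius_px = bubble_radius_px, baseline_row = baseline_row,
         image_dim = as.integer(image_dim), center = center,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "bubble_phantom_spec")
}

#' Render a captive-bubble phantom image
#'
#' @param spec a [bubble_phantom_spec()].
#' @param background,bubble_level,solid_level intensity counts for the three
#'   regions (8-bit).
#' @return list with `image` (a [gray_image()]), `true_angle_deg`,
#'   `baseline_row` and the `spec`.
#' @export
make_bubble_image <- function(spec, background = 220, bubble_level = 40,
                              solid_level = 100) {
  stopifnot(inherits(spec, "bubble_phantom_spec"))
  dim <- spec$image_dim
  f <- matrix(background, dim[1], dim[2])
  f[seq_len(spec$baseline_row - 1), ] <- solid_level
  d2 <- dist2_grid(dim[1], dim[2], spec$center)
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cap <- d2 <= spec$bubble_radius_px^2 & rows >= spec$baseline_row
  if (!any(cap))
    stop("degenerate cap: circle does not intersect the baseline",
         call. = FALSE)
  f[cap] <- bubble_level
  if (spec$noise_sd > 0) {
    f <- with_seed(spec$seed, f + stats::rnorm(length(f),
                                               sd = spec$noise_sd))
    f <- round(pmin(pmax(f, 0), 255))
    dim(f) <- dim
  }
  list(image = gray_image(f, bit_depth = 8L),
       true_angle_deg = spec$contact_angle_deg,
       baseline_row = spec$baseline_row, spec = spec)
}
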