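#' Diameter time series of the liquid-squeezed area
#'
#' Ordered `(time_s, diameter_mm)` samples with the air-jet interval and
#' acquisition metadata. Time 0 is anchored to jet onset, so `jet_on_s` is 0
#' for series produced by [diameter_series()].
#'
#' @param time_s strictly increasing sample times, s.
#' @param diameter_mm non-negative diameters, mm.
#' @param jet_on_s,jet_off_s jet interval on the same time axis.
#' @param scale_mm_per_px,frame_rate_hz acquisition metadata.
#' @return a `diameter_series`.
#' @export
new_diameter_series <- function(time_s, diameter_mm, jet_on_s = 0,
                                jet_off_s = 1, scale_mm_per_px = NA_real_,
                                frame_rate_hz = NA_real_) {
  stopifnot(length(time_s) == length(diameter_mm))
  if (is.unsorted(time_s, strictly = TRUE))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (any(diameter_mm < 0))
    stop("diameters must be >= 0", call. = FALSE)
  if (jet_on_s >= jet_off_s)
    stop("`jet_on_s` must precede `jet_off_s`", call. = FALSE)
  structure(
    list(samples = data.frame(time_s = time_s, diameter_mm = diameter_mm),
         jet_on_s = jet_on_s, jet_off_s = jet_off_s,
         scale_mm_per_px = scale_mm_per_px, frame_rate_hz = frame_rate_hz),
    class = "diameter_series")
}

#' @export
print.diameter_series <- function(x, ...) {
  cat(sprintf(
    "<diameter_series> %d samples on [%.3g, %.3g] s, jet [%.3g, %.3g] s, max %.3g mm\n",
    nrow(x$samples), min(x$samples$time_s), max(x$samples$time_s),
    x$jet_on_s, x$jet_off_s, max(x$samples$diameter_mm)))
  invisible(x)
}

#' Analysis windows for the wettability indexes
#'
#' The mean squeezed diameter is averaged over the later phase of the jet
#' (0.63 to 0.9 s after onset, with a 1-s jet) and the residual diameter
#' over 1.23 to 1.5 s, after the jet has ceased. Both windows are closed.
#'
#' @param mean_window,residual_window numeric length-2 window bounds, s.
#' @param jet_duration_s jet duration, s.
#' @return an `analysis_windows` list.
#' @export
analysis_windows <- function(mean_window = c(0.63, 0.9),
                             residual_window = c(1.23, 1.5),
                             jet_duration_s = 1.0) {
  stopifnot(mean_window[1] < mean_window[2],
            residual_window[1] < residual_window[2])
  if (mean_window[2] > jet_duration_s)
    stop("mean window must lie within the jet-on interval", call. = FALSE)
  if (residual_window[1] < jet_duration_s)
    stop("residual window must start after the jet stops", call. = FALSE)
  structure(list(mean_window = mean_window,
                 residual_window = residual_window,
                 jet_duration_s = jet_duration_s),
            class = "analysis_windows")
}

# closed-window membership with a small timestamp tolerance
in_window <- function(t, window, tol = 1e-9) {
  t >= window[1] - tol & t <= window[2] + tol
}

#' Segment the liquid-squeezed (dry) region in one frame
#'
#' Thresholds the absolute difference between the frame and a pre-jet
#' baseline (Otsu's method unless a manual threshold is given), closes small
#' gaps morphologically, labels connected components and keeps the one
#' containing the nozzle axis, or the nearest by centroid if none contains
#' it. An empty mask (no squeezed area) is a valid result.
#'
#' @param frame,baseline count matrices or [gray_image()]s of equal shape.
#' @param nozzle_axis numeric length-2 (row, col) of the air-nozzle axis.
#' @param threshold optional manual difference threshold, counts; default
#'   Otsu on the absolute difference, floored at `min_diff`.
#' @param min_diff smallest difference treated as signal, counts; guards
#'   Otsu against splitting pure noise when no dry area exists (default a
#'   quarter of the nominal dry/wet contrast step).
#' @param closing_radius radius of the morphological closing brush, px.
#' @param min_area_px components smaller than this are rejected as noise
#'   speckle, so a frame with no dry area yields an exactly empty mask.
#' @return logical matrix.
#' @export
segment_squeezed_region <- function(frame, baseline, nozzle_axis,
                                    threshold = NULL, min_diff = 20,
                                    closing_radius = 2, min_area_px = 9) {
  if (inherits(frame, "gray_image")) frame <- frame$intensity
  if (inherits(baseline, "gray_image")) baseline <- baseline$intensity
  if (!all(dim(frame) == dim(baseline)))
    stop("frame and baseline must have the same shape", call. = FALSE)
  d <- abs(frame - baseline)
  if (is.null(threshold)) {
    rng <- range(d)
    threshold <- if (rng[2] <= min_diff) min_diff
      else max(255 * EBImage::otsu(EBImage::Image(d / 255),
                                   range = c(0, 1)), min_diff)
  }
  mask <- d > threshold
  if (!any(mask)) return(mask)
  brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
  mask <- EBImage::closing(mask, brush) > 0
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0], nbins = n)
  small <- which(areas < min_area_px)
  if (length(small) > 0L) {
    lab[lab %in% small] <- 0L
    if (max(lab) == 0L || all(areas < min_area_px)) return(mask & FALSE)
  }
  labels <- setdiff(sort(unique(as.vector(lab))), 0L)
  at_nozzle <- lab[round(nozzle_axis[1]), round(nozzle_axis[2])]
  keep <- if (at_nozzle > 0) at_nozzle else {
    cent <- vapply(labels, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      sqrt((mean(idx[, 1]) - nozzle_axis[1])^2 +
           (mean(idx[, 2]) - nozzle_axis[2])^2)
    }, numeric(1))
    labels[which.min(cent)]
  }
  lab == keep
}

#' Equivalent-circle diameter of a segmented region
#'
#' The default diameter definition is the equivalent-circle diameter
#' `2 * sqrt(area / pi) * scale`; `method = "feret"` instead reports the
#' maximum caliper (Feret) diameter of the region's convex hull.
#'
#' @param mask logical matrix; an empty mask has diameter 0.
#' @param scale_mm_per_px positive spatial scale.
#' @param method `"equivalent"` (default) or `"feret"`.
#' @return diameter in mm.
#' @export
diameter_from_mask <- function(mask, scale_mm_per_px,
                               method = c("equivalent", "feret")) {
  method <- match.arg(method)
  if (!is.numeric(scale_mm_per_px) || scale_mm_per_px <= 0)
    stop("`scale_mm_per_px` must be positive", call. = FALSE)
  a <- sum(mask)
  if (a == 0L) return(0)
  if (method == "equivalent")
    return(2 * sqrt(a / pi) * scale_mm_per_px)
  idx <- which(mask, arr.ind = TRUE)
  hull <- idx[grDevices::chull(idx[, 1], idx[, 2]), , drop = FALSE]
  max(stats::dist(hull)) * scale_mm_per_px
}

#' Extract the squeezed-diameter time series from a video
#'
#' The baseline is the mean of all frames acquired before jet onset (at
#' least one is required). Each frame is segmented against the baseline and
#' reduced to a diameter; sample times are re-anchored so that t = 0 is the
#' manifest's jet-onset timestamp.
#'
#' @param video a `squeeze_video` (from [make_squeeze_video()] or
#'   [read_squeeze_video()]).
#' @param threshold,min_diff,closing_radius,min_area_px passed to
#'   [segment_squeezed_region()].
#' @param method diameter definition, see [diameter_from_mask()].
#' @return a [diameter_series][new_diameter_series()].
#' @export
diameter_series <- function(video, threshold = NULL, min_diff = 20,
                            closing_radius = 2, min_area_px = 9,
                            method = c("equivalent", "feret")) {
  stopifnot(inherits(video, "squeeze_video"))
  method <- match.arg(method)
  pre <- video$times_s < video$jet_on_s
  if (!any(pre))
    stop("no pre-jet frame available for the baseline", call. = FALSE)
  baseline <- Reduce(`+`, video$frames[pre]) / sum(pre)
  d_mm <- vapply(video$frames, function(f) {
    m <- segment_squeezed_region(f, baseline, video$nozzle_axis,
                                 threshold = threshold, min_diff = min_diff,
                                 closing_radius = closing_radius,
                                 min_area_px = min_area_px)
    diameter_from_mask(m, video$scale_mm_per_px, method = method)
  }, numeric(1))
  new_diameter_series(
    time_s = video$times_s - video$jet_on_s, diameter_mm = d_mm,
    jet_on_s = 0, jet_off_s = video$jet_off_s - video$jet_on_s,
    scale_mm_per_px = video$scale_mm_per_px,
    frame_rate_hz = video$frame_rate_hz)
}

#' Mean squeezed diameter during the air-jet phase
#'
#' Arithmetic mean of the diameters whose timestamps fall in the closed
#' mean window (default 0.63 to 0.9 s after jet onset) — the primary
#' wettability index: a smaller value indicates higher wettability.
#'
#' @param series a `diameter_series`.
#' @param windows an [analysis_windows()].
#' @return mean diameter, mm.
#' @export
mean_squeezed_diameter <- function(series, windows = analysis_windows()) {
  stopifnot(inherits(series, "diameter_series"))
  sel <- in_window(series$samples$time_s, windows$mean_window)
  if (!any(sel))
    stop(sprintf("no samples in the mean window [%g, %g] s",
                 windows$mean_window[1], windows$mean_window[2]),
         call. = FALSE)
  mean(series$samples$diameter_mm[sel])
}

#' Residual squeezed diameter after the air-jet ceases
#'
#' Arithmetic mean of the diameters in the closed residual window (default
#' 1.23 to 1.5 s after jet onset). When the liquid fully re-covers the
#' surface every in-window diameter is 0 and the index is exactly 0.
#'
#' @inheritParams mean_squeezed_diameter
#' @return residual diameter, mm.
#' @export
residual_diameter <- function(series, windows = analysis_windows()) {
  stopifnot(inherits(series, "diameter_series"))
  sel <- in_window(series$samples$time_s, windows$residual_window)
  if (!any(sel))
    stop(sprintf("no samples in the residual window [%g, %g] s",
                 windows$residual_window[1], windows$residual_window[2]),
         call. = FALSE)
  mean(series$samples$diameter_mm[sel])
}

#' Dominant oscillation frequency of the squeezed diameter
#'
#' Periodogram of the mean-detrended diameters inside the window (default
#' the full jet-on interval). The dominant nonzero-frequency peak is
#' reported when its power exceeds `peak_factor` times the median spectral
#' power; otherwise `NA` (no oscillation).
#'
#' @param series a `diameter_series` with a known frame rate.
#' @param window numeric length-2 time window, s.
#' @param peak_factor peak-to-median power ratio required to report a
#'   frequency.
#' @param candidate_band_hz optional length-2 band of physically expected
#'   frequencies; an error is raised if the frame rate cannot resolve it
#'   (below twice its upper edge).
#' @param min_sd_mm amplitude floor: variation below this (about one pixel
#'   pitch at the default scale) is not a resolvable oscillation and yields
#'   `NA`.
#' @return frequency in Hz, or `NA_real_`.
#' @export
oscillation_frequency <- function(series, window = NULL, peak_factor = 4,
                                  candidate_band_hz = NULL,
                                  min_sd_mm = 0.05) {
  stopifnot(inherits(series, "diameter_series"))
  if (is.null(window)) window <- c(series$jet_on_s, series$jet_off_s)
  fs <- series$frame_rate_hz
  if (is.na(fs)) {
    dt <- diff(series$samples$time_s)
    if (max(dt) - min(dt) > 1e-6)
      stop("series is not uniformly sampled and has no frame rate",
           call. = FALSE)
    fs <- 1 / mean(dt)
  }
  if (!is.null(candidate_band_hz) && fs < 2 * max(candidate_band_hz))
    stop("frame rate ", fs, " Hz cannot resolve frequencies up to ",
         max(candidate_band_hz), " Hz (sub-Nyquist)", call. = FALSE)
  sel <- in_window(series$samples$time_s, window)
  x <- series$samples$diameter_mm[sel]
  if (length(x) < 8L)
    stop("need at least 8 samples in the window for a periodogram",
         call. = FALSE)
  x <- x - mean(x)
  if (all(x == 0) || stats::sd(x) < min_sd_mm) return(NA_real_)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, demean = TRUE, fast = FALSE,
                          plot = FALSE)
  if (!is.null(candidate_band_hz)) {
    keep <- sp$freq >= candidate_band_hz[1] & sp$freq <= candidate_band_hz[2]
    if (!any(keep)) return(NA_real_)
    spec <- sp$spec[keep]; freq <- sp$freq[keep]
  } else {
    spec <- sp$spec; freq <- sp$freq
  }
  peak <- which.max(spec)
  if (spec[peak] < peak_factor * stats::median(sp$spec)) return(NA_real_)
  freq[peak]
}

#' Both wettability indexes for one experiment
#'
#' @inheritParams mean_squeezed_diameter
#' @param with_frequency also estimate the oscillation frequency over the
#'   steady later phase of the jet (the last 55 percent of the jet-on
#'   interval, clear of the opening and spreading ramps).
#' @return a `wettability_indexes` list: `mean_squeezed_diameter_mm`,
#'   `residual_diameter_mm`, `oscillation_freq_hz`,
#'   `n_frames_mean_window`, `n_frames_residual_window`.
#' @export
wettability_indexes <- function(series, windows = analysis_windows(),
                                with_frequency = TRUE) {
  stopifnot(inherits(series, "diameter_series"))
  n_mean <- sum(in_window(series$samples$time_s, windows$mean_window))
  n_res <- sum(in_window(series$samples$time_s, windows$residual_window))
  freq <- NA_real_
  if (with_frequency) {
    fw <- series$jet_on_s +
      c(0.45, 1) * (series$jet_off_s - series$jet_on_s)
    freq <- tryCatch(oscillation_frequency(series, window = fw),
                     error = function(e) NA_real_)
  }
  structure(
    list(mean_squeezed_diameter_mm = mean_squeezed_diameter(series, windows),
         residual_diameter_mm = residual_diameter(series, windows),
         oscillation_freq_hz = freq,
         n_frames_mean_window = n_mean, n_frames_residual_window = n_res),
    class = "wettability_indexes")
}

#' @export
print.wettability_indexes <- function(x, ...) {
  cat(sprintf(
    "<wettability_indexes> mean %.3g mm (n=%d), residual %.3g mm (n=%d)%s\n",
    x$mean_squeezed_diameter_mm, x$n_frames_mean_window,
    x$residual_diameter_mm, x$n_frames_residual_window,
    if (is.na(x$oscillation_freq_hz)) ""
    else sprintf(", oscillation %.3g Hz", x$oscillation_freq_hz)))
  invisible(x)
}
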