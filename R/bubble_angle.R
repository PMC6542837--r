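#' Detect the captive-bubble silhouette against a baseline
#'
#' Works on the image region at and below the baseline row (the liquid side
#' of the solid surface). The region is binarised with Otsu's method; the
#' background class is identified as the majority class along the frame
#' border of that region, and the bubble is the largest foreground
#' connected component touching the baseline.
#'
#' @param image a [gray_image()].
#' @param baseline_row pixel row of the solid surface.
#' @param threshold optional manual intensity threshold, counts.
#' @return a `bubble_profile`: list with `contour` (n x 2 matrix of (row,
#'   col) boundary pixels in full-image coordinates), `baseline_row`, and
#'   `scale_mm_per_px`.
#' @export
detect_bubble_profile <- function(image, baseline_row, threshold = NULL) {
  stopifnot(inherits(image, "gray_image"))
  m <- image$intensity
  if (baseline_row < 1 || baseline_row > nrow(m) - 2)
    stop("baseline row outside the frame", call. = FALSE)
  sub <- m[baseline_row:nrow(m), , drop = FALSE]
  full <- 2^image$bit_depth - 1
  if (diff(range(sub)) < 2)
    stop("no bubble detected: region below baseline has no contrast",
         call. = FALSE)
  thr <- if (is.null(threshold))
    full * EBImage::otsu(EBImage::Image(sub / full), range = c(0, 1))
  else threshold
  dark <- sub < thr
  border <- c(dark[, 1], dark[, ncol(dark)], dark[nrow(dark), ])
  bubble_mask <- if (mean(border) > 0.5) !dark else dark
  lab <- EBImage::bwlabel(bubble_mask)
  n <- max(lab)
  if (n == 0L)
    stop("no bubble detected below the baseline", call. = FALSE)
  touching <- sort(unique(as.vector(lab[1:min(2, nrow(lab)), ])))
  touching <- touching[touching > 0]
  if (length(touching) == 0L)
    stop("no component touching the baseline", call. = FALSE)
  sizes <- vapply(touching, function(k) sum(lab == k), numeric(1))
  comp <- lab == touching[which.max(sizes)]
  # boundary pixels: inside the component with a 4-neighbour outside
  pad <- matrix(FALSE, nrow(comp) + 2, ncol(comp) + 2)
  pad[2:(nrow(comp) + 1), 2:(ncol(comp) + 1)] <- comp
  core <- pad[1:nrow(comp), 2:(ncol(comp) + 1)] &
          pad[3:(nrow(comp) + 2), 2:(ncol(comp) + 1)] &
          pad[2:(nrow(comp) + 1), 1:ncol(comp)] &
          pad[2:(nrow(comp) + 1), 3:(ncol(comp) + 2)]
  boundary <- comp & !core
  idx <- which(boundary, arr.ind = TRUE)
  if (nrow(idx) < 10L)
    stop("bubble contour too small (fewer than 10 boundary pixels)",
         call. = FALSE)
  contour <- cbind(row = idx[, 1] + baseline_row - 1L, col = idx[, 2])
  structure(
    list(contour = contour, baseline_row = baseline_row,
         scale_mm_per_px = image$scale_mm_per_px),
    class = "bubble_profile")
}

# algebraic (Kasa) least-squares circle through (row, col) points
fit_circle <- function(pts) {
  r <- pts[, 1]; c <- pts[, 2]
  z <- r^2 + c^2
  fit <- stats::lm(z ~ r + c)
  b <- stats::coef(fit)
  center <- c(b[["r"]] / 2, b[["c"]] / 2)
  rad2 <- b[["(Intercept)"]] + sum(center^2)
  if (!is.finite(rad2) || rad2 <= 0)
    stop("degenerate circle fit", call. = FALSE)
  radius <- sqrt(rad2)
  resid <- sqrt((r - center[1])^2 + (c - center[2])^2) - radius
  list(center = center, radius = radius,
       rms_residual = sqrt(mean(resid^2)))
}

#' Contact angle from a circular-arc fit of the bubble profile
#'
#' Fits a circle to the contour by algebraic least squares, excluding points
#' within `baseline_band_px` of the baseline (where the silhouette is cut by
#' the solid, not circular). With the fitted centre a signed distance `h`
#' beyond the baseline into the bubble phase and radius `r`, the contact
#' angle measured through the bubble is `90 + asin(h/r)` degrees. Gravity
#' distortion of the 2–5 uL bubbles is neglected (circle, not
#' Young–Laplace); `fit_residual` exposes violations of that model.
#'
#' Note the convention: this is the bubble-side angle, under which a
#' *smaller* value indicates a *more hydrophobic* surface. Use
#' [water_side_angle()] for the complementary liquid-side convention.
#'
#' @param profile a `bubble_profile` from [detect_bubble_profile()].
#' @param baseline_band_px exclusion band half-width around the baseline,
#'   px.
#' @return an `angle_result`: list with `angle_deg`, `fit_residual` (RMS
#'   px), `center`, `radius_px`.
#' @export
contact_angle_circle_fit <- function(profile, baseline_band_px = 5) {
  stopifnot(inherits(profile, "bubble_profile"))
  pts <- profile$contour
  keep <- pts[, 1] > profile$baseline_row + baseline_band_px
  if (sum(keep) < 5L)
    stop("too few contour points beyond the baseline band for a circle fit",
         call. = FALSE)
  fit <- fit_circle(pts[keep, , drop = FALSE])
  h <- fit$center[1] - profile$baseline_row  # >0: centre in bubble phase
  if (abs(h) >= fit$radius)
    stop("fitted circle does not intersect the baseline", call. = FALSE)
  angle <- 90 + asin(h / fit$radius) * 180 / pi
  structure(
    list(angle_deg = angle, fit_residual = fit$rms_residual,
         center = fit$center, radius_px = fit$radius),
    class = "angle_result")
}

#' @export
print.angle_result <- function(x, ...) {
  cat(sprintf("<angle_result> %.2f deg (bubble side), RMS residual %.3g px\n",
              x$angle_deg, x$fit_residual))
  invisible(x)
}

#' Convert a bubble-side contact angle to the water-side convention
#'
#' @param angle_deg bubble-side angle in degrees.
#' @return `180 - angle_deg`.
#' @export
water_side_angle <- function(angle_deg) 180 - angle_deg

#' Contact angle of a captive bubble in one image
#'
#' Convenience wrapper: [detect_bubble_profile()] then
#' [contact_angle_circle_fit()].
#'
#' @inheritParams detect_bubble_profile
#' @inheritParams contact_angle_circle_fit
#' @return an `angle_result`.
#' @export
measure_contact_angle <- function(image, baseline_row, threshold = NULL,
                                  baseline_band_px = 5) {
  contact_angle_circle_fit(
    detect_bubble_profile(image, baseline_row, threshold = threshold),
    baseline_band_px = baseline_band_px)
}
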