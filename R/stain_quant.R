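#' Remove display-gamma compensation from a scanner image
#'
#' Scanner images are gamma-encoded for visual display. The decompensated
#' brightness of a pixel with counts \eqn{I} at bit depth \eqn{b} is
#' \deqn{I' = -\frac{\gamma}{\ln 10}\,\ln\!\left(\frac{I}{2^b - 1}\right),}
#' a dimensionless optical-density-like quantity: 0 at full-scale white and
#' strictly decreasing in \eqn{I}. Counts below 1 are clipped to 1 before the
#' logarithm (the transform diverges at 0 and a saturated-black pixel carries
#' no gradation).
#'
#' @param image a [gray_image()].
#' @param gamma positive display gamma of the scanner (1.8 for the reference
#'   flatbed scanner).
#' @return An `od_map`: list with `i_prime` (matrix), `gamma`, `bit_depth`,
#'   `roi_mask` (initially all `TRUE`), and a `density` slot filled later by
#'   [stain_density()].
#' @seealso [fit_calibration()], [stain_density()]
#' @export
decompensate <- function(image, gamma = 1.8) {
  stopifnot(inherits(image, "gray_image"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a positive scalar", call. = FALSE)
  full <- 2^image$bit_depth - 1
  i <- pmax(image$intensity, 1)
  i_prime <- -(gamma / log(10)) * log(i / full)
  structure(
    list(i_prime = i_prime, density = NULL,
         roi_mask = matrix(TRUE, nrow(i_prime), ncol(i_prime)),
         gamma = gamma, bit_depth = image$bit_depth),
    class = "od_map")
}

#' @export
print.od_map <- function(x, ...) {
  cat(sprintf("<od_map> %d x %d px, gamma %.3g, I' range [%.4g, %.4g], ROI %d px%s\n",
              nrow(x$i_prime), ncol(x$i_prime), x$gamma,
              min(x$i_prime), max(x$i_prime), sum(x$roi_mask),
              if (is.null(x$density)) "" else ", density calibrated"))
  invisible(x)
}

#' Calibrate decompensated brightness to optical density
#'
#' Ordinary least-squares fit of the line \eqn{d = c_1 I' + c_0} through
#' measurements of neutral-density (ND) filter standards of known OD. The
#' reference standards are Nikon ND filters No. 4, 8 and 16 with OD 0.6, 0.9
#' and 1.2.
#'
#' @param i_prime_readings numeric vector of mean decompensated brightness per
#'   standard.
#' @param od_standards numeric vector of the standards' optical densities.
#' @return A `calibration_fit`: list with `c0`, `c1`, `r_squared`,
#'   `n_standards`.
#' @export
fit_calibration <- function(i_prime_readings, od_standards) {
  x <- as.numeric(i_prime_readings)
  y <- as.numeric(od_standards)
  if (length(x) != length(y) || length(x) < 2L)
    stop("need matched readings and standards, at least 2 of each",
         call. = FALSE)
  if (anyDuplicated(y))
    stop("OD standards must be distinct", call. = FALSE)
  if (max(x) - min(x) <= 0)
    stop("all I' readings identical; calibration line is undetermined",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(c0 = unname(stats::coef(fit)[1]), c1 = unname(stats::coef(fit)[2]),
         r_squared = min(max(r2, 0), 1), n_standards = length(x)),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> d = %.6g * I' + %.6g (r^2 = %.6g, n = %d)\n",
              x$c1, x$c0, x$r_squared, x$n_standards))
  invisible(x)
}

#' Centre-half-radius analysis region of a dish image
#'
#' The analysis area is the disc of half the dish-bottom radius around the
#' dish centre, which avoids the meniscus ring at the dish wall. The mask is
#' `TRUE` exactly for pixels whose centre lies within `dish_radius_px / 2` of
#' `dish_center`.
#'
#' @param image a [gray_image()].
#' @param dish_center numeric length-2, (row, col) of the dish centre in
#'   pixels.
#' @param dish_radius_px dish-bottom radius in pixels.
#' @return logical matrix of the same shape as the image.
#' @export
extract_roi <- function(image, dish_center, dish_radius_px) {
  stopifnot(inherits(image, "gray_image"))
  r <- dish_radius_px / 2
  nr <- nrow(image$intensity); nc <- ncol(image$intensity)
  if (dish_center[1] - r < 1 || dish_center[1] + r > nr ||
      dish_center[2] - r < 1 || dish_center[2] + r > nc)
    stop("analysis disc (radius ", r, " px) does not fit in the frame",
         call. = FALSE)
  dist2_grid(nr, nc, dish_center) <= r^2
}

#' Locate a dish by its circular edge
#'
#' Rough automatic dish geometry for when the centre and radius are not
#' supplied: strong gradient-magnitude pixels (central differences) are
#' treated as edge candidates, the centre is their centroid and the radius
#' the median centroid distance, constrained to a radius band. Manual
#' geometry always takes precedence in the pipeline runners.
#'
#' @param image a [gray_image()].
#' @param radius_band numeric length-2, admissible dish radii in pixels.
#' @param edge_quantile gradient-magnitude quantile above which a pixel votes.
#' @return list with `center` (row, col) and `radius_px`.
#' @export
detect_dish_circle <- function(image, radius_band, edge_quantile = 0.98) {
  stopifnot(inherits(image, "gray_image"))
  m <- image$intensity
  gr <- m * 0; gc <- m * 0
  gr[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
  gc[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / 2
  mag <- sqrt(gr^2 + gc^2)
  thr <- stats::quantile(mag, edge_quantile)
  idx <- which(mag >= thr & mag > 0, arr.ind = TRUE)
  if (nrow(idx) < 8L)
    stop("no circular edge found: too few strong-gradient pixels",
         call. = FALSE)
  center <- colMeans(idx)
  d <- sqrt((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2)
  keep <- d >= radius_band[1] & d <= radius_band[2]
  if (!any(keep))
    stop("no edge pixels inside the configured radius band", call. = FALSE)
  radius <- stats::median(d[keep])
  list(center = unname(center), radius_px = unname(radius))
}

#' Calibrated stain density over the analysis region
#'
#' Applies the calibration line \eqn{d = c_1 I' + c_0} to every ROI pixel and
#' summarises the dish by the arithmetic mean density over the ROI.
#'
#' @param od an `od_map` from [decompensate()].
#' @param fit a `calibration_fit`.
#' @param roi_mask optional logical matrix replacing the map's ROI.
#' @param dish_id,condition,day optional labels carried into the result.
#' @return A `stain_result`: list with `mean_density`, the updated `od_map`
#'   (with `density` filled), and the labels. `area_ratio_pct` and
#'   `threshold` are `NA` until [area_ratio()] is applied.
#' @export
stain_density <- function(od, fit, roi_mask = NULL,
                          dish_id = NA_character_, condition = NA_character_,
                          day = NA_integer_) {
  stopifnot(inherits(od, "od_map"), inherits(fit, "calibration_fit"))
  if (!is.null(roi_mask)) {
    stopifnot(is.logical(roi_mask),
              all(dim(roi_mask) == dim(od$i_prime)))
    od$roi_mask <- roi_mask
  }
  if (!any(od$roi_mask))
    stop("ROI is empty; no pixels to analyse", call. = FALSE)
  density <- fit$c1 * od$i_prime + fit$c0
  density[!od$roi_mask] <- NA_real_
  od$density <- density
  structure(
    list(mean_density = mean(density[od$roi_mask]),
         area_ratio_pct = NA_real_, threshold = NA_real_, od = od,
         dish_id = dish_id, condition = condition, day = day),
    class = "stain_result")
}

#' @export
print.stain_result <- function(x, ...) {
  cat(sprintf("<stain_result> %s: mean density %.4g OD%s\n",
              if (is.na(x$dish_id)) "dish" else x$dish_id, x$mean_density,
              if (is.na(x$area_ratio_pct)) ""
              else sprintf(", %.3g%% stained above %.4g", x$area_ratio_pct,
                           x$threshold)))
  invisible(x)
}

#' Stained/unstained density threshold from initial and incubated dishes
#'
#' The per-pixel stained/unstained cut is the midpoint between the average of
#' the initial-state dish mean densities and the average of the incubated
#' dish mean densities.
#'
#' @param initial_mean_densities numeric vector of per-dish mean densities at
#'   the initial state.
#' @param incubated_mean_densities numeric vector after incubation.
#' @return scalar threshold in OD units.
#' @export
compute_threshold <- function(initial_mean_densities,
                              incubated_mean_densities) {
  if (length(initial_mean_densities) == 0L ||
      length(incubated_mean_densities) == 0L)
    stop("both dish groups must be non-empty", call. = FALSE)
  (mean(initial_mean_densities) + mean(incubated_mean_densities)) / 2
}

#' Percent stained area over the analysis region
#'
#' Fraction of ROI pixels whose calibrated density strictly exceeds the
#' threshold, as a percentage. Ties count as unstained (measure-zero on real
#' data; the convention is simply fixed).
#'
#' @param od an `od_map` with `density` populated (see [stain_density()]), or
#'   a `stain_result`.
#' @param threshold scalar density threshold in OD units.
#' @return For an `od_map`, the percentage in `[0, 100]`; for a
#'   `stain_result`, the result with `area_ratio_pct` and `threshold` filled.
#' @export
area_ratio <- function(od, threshold) {
  if (inherits(od, "stain_result")) {
    res <- od
    res$area_ratio_pct <- area_ratio(res$od, threshold)
    res$threshold <- threshold
    return(res)
  }
  stopifnot(inherits(od, "od_map"))
  if (is.null(od$density))
    stop("density not populated; run stain_density() first", call. = FALSE)
  if (!any(od$roi_mask))
    stop("ROI is empty", call. = FALSE)
  d <- od$density[od$roi_mask]
  100 * sum(d > threshold) / length(d)
}
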