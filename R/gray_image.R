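#' Grayscale intensity image
#'
#' Light container for a 2-D grid of integer intensity counts, the raw
#' observable of every pipeline in the package. Counts live on
#' `[0, 2^bit_depth - 1]`; an optional spatial scale (mm per pixel) travels
#' with the image so downstream diameters can be reported in millimetres.
#'
#' @param intensity numeric matrix of counts (rows = image rows).
#' @param bit_depth integer, 8 or 16.
#' @param scale_mm_per_px optional positive scalar, mm per pixel.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(intensity, bit_depth = 8L, scale_mm_per_px = NULL) {
  if (!is.matrix(intensity) || length(intensity) == 0L)
    stop("`intensity` must be a non-empty matrix", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  full <- 2^bit_depth - 1
  if (any(intensity < 0) || any(intensity > full))
    stop("intensity counts must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  if (!is.null(scale_mm_per_px) && scale_mm_per_px <= 0)
    stop("`scale_mm_per_px` must be positive", call. = FALSE)
  structure(
    list(intensity = intensity, bit_depth = as.integer(bit_depth),
         scale_mm_per_px = scale_mm_per_px),
    class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %d-bit, counts [%g, %g]%s\n",
              nrow(x$intensity), ncol(x$intensity), x$bit_depth,
              min(x$intensity), max(x$intensity),
              if (is.null(x$scale_mm_per_px)) ""
              else sprintf(", %.4g mm/px", x$scale_mm_per_px)))
  invisible(x)
}

#' Collapse an RGB array to grayscale with Rec. 601 luma weights
#'
#' @param arr numeric array, either a matrix (returned as-is) or an
#'   `h x w x 3` (or 4, alpha ignored) array on any common scale.
#' @return a matrix on the same scale as the input channels.
#' @export
rgb_to_gray <- function(arr) {
  if (is.matrix(arr)) return(arr)
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L)
    return(0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3])
  if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) return(arr[, , 1])
  stop("cannot interpret array with dim ", paste(dim(arr), collapse = "x"),
       " as an image", call. = FALSE)
}

#' Read a PNG or TIFF file as a `gray_image`
#'
#' RGB inputs are collapsed with [rgb_to_gray()]; values are rescaled from
#' the decoder's `[0, 1]` range to integer counts at the requested bit depth.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @inheritParams gray_image
#' @export
read_gray_image <- function(path, bit_depth = 8L, scale_mm_per_px = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext, call. = FALSE))
  g <- rgb_to_gray(arr)
  counts <- round(g * (2^bit_depth - 1))
  gray_image(counts, bit_depth = bit_depth, scale_mm_per_px = scale_mm_per_px)
}

#' Write a `gray_image` to PNG or TIFF
#'
#' @param image a `gray_image`.
#' @param path output path; format chosen from the extension.
#' @export
write_gray_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  norm <- image$intensity / (2^image$bit_depth - 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(norm, path),
    tif  = ,
    tiff = tiff::writeTIFF(norm, path,
                           bits.per.sample = image$bit_depth),
    stop("unsupported image extension: ", ext, call. = FALSE))
  invisible(path)
}

# Squared-distance grid from a centre, in pixel units; pixel centres are at
# integer (row, col) coordinates.
dist2_grid <- function(nrow, ncol, center) {
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2
}

# Evaluate a function with a temporary RNG seed, restoring prior state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
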