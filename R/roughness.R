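# Wrinkle-restricted roughness statistics computed on the grayscale of the
# ORIGINAL frame (never the amplified one):
#   Ra = (1 / (w h)) * sum_ij Wp(G_ij)          (mean over the WHOLE image)
#   Wp(G_ij) = G_ij inside the wrinkle mask, 0 outside
#   Rq = sqrt( sum_ij Wp(G_ij)^2 / (w h) )      (sqrt optional, see below)
#   Wa = |mask| * pixel_area_mm2
# Both Ra and Rq are normalised by the total pixel count w*h, not by the
# foreground count — this differs from the classical profilometric Ra and
# makes the statistics sensitive to wrinkle extent as well as tone.

#' Masked gray field (wrinkle-pixel function)
#'
#' Returns the gray value inside the wrinkle mask and 0 outside — the
#' Wp function feeding the roughness sums.
#'
#' @param gray H x W numeric matrix of gray values in 0-255.
#' @param mask Logical H x W matrix, `TRUE` = wrinkle.
#' @return H x W numeric matrix.
#' @export
wrinkle_pixels <- function(gray, mask) {
  m <- as_logical_mask(mask)
  if (!is.matrix(gray) || !identical(dim(gray), dim(m)))
    stop("`gray` and `mask` must be matrices of identical dimensions",
         call. = FALSE)
  gray * m
}

#' Image-based average roughness Ra
#'
#' Sum of grayscale values over the wrinkle pixels divided by the *total*
#' pixel count `w * h` (not the foreground count).  Dimensionless, in gray
#' levels; an empty mask gives 0.
#'
#' @inheritParams wrinkle_pixels
#' @return Numeric scalar in `[0, 255]`.
#' @examples
#' g <- matrix(c(100, 50, 200, 250), 2, 2)
#' m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
#' average_roughness(g, m)  # (100 + 50) / 4 = 37.5
#' @export
average_roughness <- function(gray, mask) {
  wp <- wrinkle_pixels(gray, mask)
  sum(wp) / length(wp)
}

#' Image-based root-mean-square roughness Rq
#'
#' Quadratic analogue of [average_roughness()]: the mean of squared masked
#' gray values over the total pixel count.  By default the square root is
#' applied, giving a true RMS in gray levels; `take_sqrt = FALSE` returns
#' the un-rooted mean of squares for compatibility with conventions that
#' omit the radical.
#'
#' @inheritParams wrinkle_pixels
#' @param take_sqrt Apply the square root (default `TRUE`).
#' @return Numeric scalar; in `[0, 255]` when `take_sqrt = TRUE`.
#' @export
rms_roughness <- function(gray, mask, take_sqrt = TRUE) {
  wp <- wrinkle_pixels(gray, mask)
  msq <- sum(wp^2) / length(wp)
  if (take_sqrt) sqrt(msq) else msq
}

#' Wrinkle area Wa
#'
#' Foreground pixel count times the per-pixel area of the device geometry,
#' in mm^2.
#'
#' @param mask Logical H x W matrix, `TRUE` = wrinkle.
#' @param geometry A [device_geometry()]; its `pixel_area_mm2` is used.
#' @return Numeric scalar, mm^2.
#' @export
wrinkle_area <- function(mask, geometry = device_geometry()) {
  m <- as_logical_mask(mask)
  stopifnot(inherits(geometry, "device_geometry"))
  sum(m) * geometry$pixel_area_mm2
}

#' Segment and quantify roughness in one call
#'
#' Runs [segment_wrinkles()] on the frame, converts the *original* image
#' (not the amplified one) to grayscale, and evaluates Ra, Rq and Wa over
#' the detected wrinkle mask.
#'
#' @param img An H x W x 3 array of 0-255 intensities.
#' @param config A [segmentation_config()].
#' @param geometry A [device_geometry()].
#' @param take_sqrt Passed to [rms_roughness()].
#' @return An object of class `roughness_result` with fields `ra`, `rq`,
#'   `wa`, `wrinkle_pixel_count`, `width_px`, `height_px`,
#'   `pixel_area_mm2` and the mask itself in `mask`.
#' @examples
#' img <- array(30, dim = c(12, 16, 3))
#' res <- analyze_image(img)
#' res$ra   # 30: uniform dark frame, full mask
#' @export
analyze_image <- function(img, config = segmentation_config(),
                          geometry = device_geometry(), take_sqrt = TRUE) {
  validate_rgb(img)
  mask <- segment_wrinkles(img, config)
  gray <- to_grayscale(img)
  structure(list(
    ra = average_roughness(gray, mask),
    rq = rms_roughness(gray, mask, take_sqrt = take_sqrt),
    wa = wrinkle_area(mask, geometry),
    wrinkle_pixel_count = sum(mask),
    width_px = ncol(mask),
    height_px = nrow(mask),
    pixel_area_mm2 = geometry$pixel_area_mm2,
    mask = mask
  ), class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf(
    "Roughness over %d x %d px frame: %d wrinkle px (%.1f%%)\n  Ra = %.4f  Rq = %.4f  Wa = %.6f mm^2\n",
    x$width_px, x$height_px, x$wrinkle_pixel_count,
    100 * x$wrinkle_pixel_count / (x$width_px * x$height_px),
    x$ra, x$rq, x$wa))
  invisible(x)
}

#' @export
as.data.frame.roughness_result <- function(x, ...) {
  data.frame(wrinkle_pixel_count = x$wrinkle_pixel_count,
             ra = x$ra, rq = x$rq, wa = x$wa,
             width_px = x$width_px, height_px = x$height_px,
             pixel_area_mm2 = x$pixel_area_mm2)
}
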