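# Coordinate convention used throughout the package: images are row-major
# H x W (x 3) arrays indexed [row, col(, channel)], 0-255 intensities,
# origin at the top-left corner.

#' Device geometry of the dermatoscope
#'
#' Holds the acquisition geometry of the USB dermatoscope: a 1600 x 1200
#' pixel sensor imaging a 7 x 6.5 mm field of view at roughly 50x optical
#' magnification.  The per-pixel area used by [wrinkle_area()] is an
#' explicit constant (default `0.203e-4` mm^2) and is deliberately *not*
#' derived from the field-of-view fields; see Details.
#'
#' @details The default per-pixel area is the published calibration
#'   constant for this device.  Dividing the nominal field of view by the
#'   pixel count would give 7 * 6.5 / (1600 * 1200) = 2.37e-5 mm^2 instead;
#'   the two disagree, and the calibration constant is kept verbatim so
#'   that wrinkle areas are comparable with values reported for the device.
#'   For images from any other instrument, supply `pixel_area_mm2`
#'   explicitly.
#'
#' @param field_width_mm,field_height_mm Field of view in mm.
#' @param res_x,res_y Sensor resolution in pixels (width, height).
#' @param pixel_area_mm2 Area of one pixel in mm^2.
#' @return An object of class `device_geometry`.
#' @examples
#' device_geometry()
#' @export
device_geometry <- function(field_width_mm = 7.0, field_height_mm = 6.5,
                            res_x = 1600L, res_y = 1200L,
                            pixel_area_mm2 = 0.203e-4) {
  stopifnot(field_width_mm > 0, field_height_mm > 0,
            res_x >= 1, res_y >= 1, pixel_area_mm2 > 0)
  structure(list(field_width_mm = field_width_mm,
                 field_height_mm = field_height_mm,
                 res_x = as.integer(res_x), res_y = as.integer(res_y),
                 pixel_area_mm2 = pixel_area_mm2),
            class = "device_geometry")
}

#' @export
print.device_geometry <- function(x, ...) {
  cat(sprintf("Dermatoscope geometry: %d x %d px over %.2f x %.2f mm (%.3g mm^2/px)\n",
              x$res_x, x$res_y, x$field_width_mm, x$field_height_mm,
              x$pixel_area_mm2))
  invisible(x)
}

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L
}

validate_rgb <- function(img, arg = "img") {
  if (!is_rgb_image(img))
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("`%s` has zero-sized dimensions", arg), call. = FALSE)
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` values must lie in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

validate_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("`%s` must be an H x W matrix", arg), call. = FALSE)
  if (is.logical(mask)) return(invisible(mask))
  if (!all(mask %in% c(0, 1, 255)))
    stop(sprintf("`%s` must be logical or strictly two-valued (0/255)", arg),
         call. = FALSE)
  invisible(mask)
}

as_logical_mask <- function(mask) {
  validate_mask(mask)
  if (is.logical(mask)) mask else mask > 0
}

#' Read a dermatoscope image
#'
#' Reads a PNG or JPEG file into an H x W x 3 integer array of 8-bit
#' intensities (0-255).  Single-channel (grayscale) inputs are replicated
#' across the three channels; an alpha channel, if present, is dropped;
#' 16-bit PNG inputs are rescaled linearly to 0-255.  The format is
#' detected from the file's magic bytes, falling back on the extension.
#'
#' TIFF input is not supported by this build; convert to PNG first.
#'
#' @param path Path to a PNG or JPEG file.
#' @return An H x W x 3 numeric array with integral values in 0-255.
#' @seealso [to_grayscale()], [save_mask()]
#' @export
load_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  fmt <- detect_image_format(path)
  raw01 <- tryCatch(
    switch(fmt,
           png  = png::readPNG(path),
           jpeg = jpeg::readJPEG(path),
           stop("unsupported image format (need PNG or JPEG): ", path,
                call. = FALSE)),
    error = function(e) stop("failed to decode image ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  # readPNG/readJPEG return values in [0,1] whatever the source bit depth,
  # so 16-bit inputs are rescaled here for free.
  px <- round(raw01 * 255)
  if (is.matrix(px)) {
    px <- array(px, dim = c(dim(px), 3L))            # replicate gray channel
  } else if (dim(px)[3] == 2L) {
    px <- array(px[, , 1L], dim = c(dim(px)[1:2], 3L))  # gray + alpha
  } else if (dim(px)[3] >= 4L) {
    px <- px[, , 1:3, drop = FALSE]                  # drop alpha
  }
  if (dim(px)[1] < 1L || dim(px)[2] < 1L)
    stop("zero-sized image: ", path, call. = FALSE)
  validate_rgb(px)
}

detect_image_format <- function(path) {
  sig <- readBin(path, "raw", n = 4L)
  if (length(sig) >= 4L && identical(sig[1:4],
        as.raw(c(0x89, 0x50, 0x4e, 0x47)))) return("png")
  if (length(sig) >= 2L && identical(sig[1:2], as.raw(c(0xff, 0xd8))))
    return("jpeg")
  switch(tolower(tools::file_ext(path)),
         png = "png", jpg = "jpeg", jpeg = "jpeg",
         stop("unsupported or corrupt image file: ", path, call. = FALSE))
}

#' Convert an RGB image to grayscale
#'
#' Luminance conversion with Rec.601 weights,
#' `gray = 0.299 R + 0.587 G + 0.114 B`, rounded to the nearest integer
#' (round-half-even, R's default) and clipped to 0-255.  The weights are
#' configurable; they must be non-negative and are normalised to sum to 1.
#'
#' @param img An H x W x 3 array of 0-255 intensities.
#' @param weights Channel weights (R, G, B).
#' @return An H x W numeric matrix with integral values in 0-255.
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(img)  # 76
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  validate_rgb(img)
  stopifnot(length(weights) == 3L, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  g <- img[, , 1L] * w[1] + img[, , 2L] * w[2] + img[, , 3L] * w[3]
  out <- pmin(pmax(round(g), 0), 255)
  dim(out) <- dim(img)[1:2]    # keep matrix shape even for 1-pixel images
  out
}

#' Write a wrinkle mask as a lossless PNG
#'
#' Foreground (wrinkle) pixels are written as 255, background as 0, in a
#' single-channel 8-bit PNG.  The file round-trips bit-exactly through
#' [load_mask()].
#'
#' @param mask Logical H x W matrix (or 0/255 matrix), foreground = wrinkle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path) {
  m <- as_logical_mask(mask)
  ok <- tryCatch({png::writePNG(m * 1.0, target = path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("cannot write mask to ", path, call. = FALSE)
  invisible(path)
}

#' Read a wrinkle mask written by [save_mask()]
#'
#' @param path Path to a single-channel PNG mask.
#' @return Logical H x W matrix, `TRUE` = wrinkle foreground.
#' @export
load_mask <- function(path) {
  if (!file.exists(path))
    stop("cannot read mask: file not found: ", path, call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px >= 0.5
}

#' Overlay a wrinkle mask on an image
#'
#' Blends foreground pixels toward `color` with weight `alpha`, leaving
#' background pixels untouched — the standard visual check that the
#' segmentation tracks the furrows in the original frame.
#'
#' @param img An H x W x 3 array of 0-255 intensities.
#' @param mask Logical H x W matrix of identical dimensions.
#' @param color RGB triple in 0-255 (default red).
#' @param alpha Blend weight in `[0, 1]`; 0 returns `img` unchanged.
#' @return An H x W x 3 array with integral values in 0-255.
#' @export
render_overlay <- function(img, mask, color = c(255, 0, 0), alpha = 0.5) {
  validate_rgb(img)
  m <- as_logical_mask(mask)
  if (!identical(dim(m), dim(img)[1:2]))
    stop("mask dimensions must match image dimensions", call. = FALSE)
  stopifnot(length(color) == 3L, all(color >= 0), all(color <= 255),
            alpha >= 0, alpha <= 1)
  out <- img
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m] <- round((1 - alpha) * plane[m] + alpha * color[ch])
    out[, , ch] <- plane
  }
  if (is.integer(img)) storage.mode(out) <- "integer"
  out
}

#' Write an RGB image as PNG
#'
#' @param img H x W x 3 array, 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  validate_rgb(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}
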