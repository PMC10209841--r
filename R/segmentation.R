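# Five-stage wrinkle segmentation:
#   Gaussian blur -> normalise to [0,1] -> power-law feature amplification
#   -> grayscale -> rescale to 0-255 -> inverted binary threshold.
# All stages are deterministic and monotone in pixel intensity, so the final
# (order-reversing) threshold makes the whole pipeline antitone: darkening a
# pixel can only grow the mask.

#' Segmentation parameters
#'
#' Bundles the three tunables of the wrinkle-detection pipeline.  The
#' defaults are the operating point established for 1600 x 1200
#' dermatoscope frames: a 37 x 37 blur kernel, amplification exponent 0.25
#' and threshold 180 on the 0-255 amplified grayscale.
#'
#' @details `sigma` controls the Gaussian width of the blur.  The default
#'   `NULL` derives it from the kernel size by the rule used by mainstream
#'   vision libraries, `sigma = 0.3 * ((k - 1)/2 - 1) + 0.8` (5.9 for
#'   k = 37), so results track implementations built on those libraries.
#'
#' @param blur_kernel Odd positive integer, side of the blur kernel.
#' @param amplification_exponent Positive exponent of the power-law
#'   amplification; values below 1 push dark tones toward 0 and light
#'   tones toward 1.
#' @param threshold Integer in 0-255; amplified gray values at or below it
#'   become wrinkle foreground (values above it are background).
#' @param sigma Gaussian sigma in pixels, or `NULL` to derive from
#'   `blur_kernel`.
#' @return An object of class `segmentation_config`.
#' @examples
#' segmentation_config()
#' @export
segmentation_config <- function(blur_kernel = 37L,
                                amplification_exponent = 0.25,
                                threshold = 180L,
                                sigma = NULL) {
  blur_kernel <- as.integer(blur_kernel)
  if (is.na(blur_kernel) || blur_kernel < 1L || blur_kernel %% 2L == 0L)
    stop("`blur_kernel` must be an odd positive integer", call. = FALSE)
  if (!is.numeric(amplification_exponent) || amplification_exponent <= 0)
    stop("`amplification_exponent` must be > 0", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
    stop("`threshold` must lie in [0, 255]", call. = FALSE)
  if (!is.null(sigma) && (!is.numeric(sigma) || sigma <= 0))
    stop("`sigma` must be > 0 or NULL", call. = FALSE)
  structure(list(blur_kernel = blur_kernel,
                 amplification_exponent = amplification_exponent,
                 threshold = as.numeric(threshold),
                 sigma = sigma),
            class = "segmentation_config")
}

#' @export
print.segmentation_config <- function(x, ...) {
  cat(sprintf(
    "Segmentation config: blur %d x %d (sigma %.3f), exponent %.3g, threshold %g\n",
    x$blur_kernel, x$blur_kernel, gaussian_sigma(x), x$amplification_exponent,
    x$threshold))
  invisible(x)
}

gaussian_sigma <- function(config) {
  if (!is.null(config$sigma)) return(config$sigma)
  k <- config$blur_kernel
  0.3 * ((k - 1) / 2 - 1) + 0.8
}

#' Normalised 1D Gaussian kernel
#'
#' Samples `exp(-(i - c)^2 / (2 sigma^2))` at integer offsets and
#' normalises to unit sum, matching the sampling rule of mainstream vision
#' libraries.
#'
#' @param size Odd positive kernel length.
#' @param sigma Gaussian sigma in pixels; `NULL` derives it from `size` as
#'   in [segmentation_config()].
#' @return Numeric vector of length `size` summing to 1.
#' @export
gaussian_kernel_1d <- function(size, sigma = NULL) {
  size <- as.integer(size)
  if (is.na(size) || size < 1L || size %% 2L == 0L)
    stop("kernel size must be an odd positive integer", call. = FALSE)
  if (is.null(sigma)) sigma <- 0.3 * ((size - 1) / 2 - 1) + 0.8
  half <- (size - 1L) / 2L
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflect-101 border indices ("gfedcb|abcdefgh|gfedcba"): mirrors about the
# edge pixel without repeating it.  `idx` may run below 1 or above n.
reflect101_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  m <- n - 1L
  i <- (idx - 1L) %% (2L * m)       # R's %% is non-negative for positive modulus
  i <- ifelse(i > m, 2L * m - i, i)
  i + 1L
}

# Separable 1D convolution along rows of a matrix with reflect-101 padding.
conv_cols_1d <- function(x, kernel) {
  n <- nrow(x)
  half <- (length(kernel) - 1L) / 2L
  pad_idx <- reflect101_index(seq.int(1L - half, n + half), n)
  xp <- x[pad_idx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (t in seq_along(kernel))
    out <- out + kernel[t] * xp[t:(t + n - 1L), , drop = FALSE]
  out
}

#' Gaussian blur
#'
#' Convolves each channel with a normalised 2D Gaussian kernel of the
#' given size, implemented separably (rows then columns) with reflect-101
#' border handling.  Uniform images pass through unchanged; a kernel of 1
#' is the identity.
#'
#' @param img An H x W x 3 array or an H x W matrix, values 0-255.
#' @param kernel Odd positive kernel side length (default 37).
#' @param sigma Gaussian sigma; `NULL` derives it from `kernel`.
#' @return Blurred array/matrix of the same dimensions (numeric, not
#'   rounded).
#' @export
gaussian_blur <- function(img, kernel = 37L, sigma = NULL) {
  k <- gaussian_kernel_1d(kernel, sigma)
  blur_plane <- function(m) t(conv_cols_1d(t(conv_cols_1d(m, k)), k))
  if (is.matrix(img)) return(blur_plane(img))
  validate_rgb(img)
  out <- img * 0
  for (ch in 1:3) out[, , ch] <- blur_plane(img[, , ch])
  out
}

#' Normalise intensities to the unit interval
#'
#' Divides every value by 255, mapping 0-255 intensities onto `[0, 1]`.
#'
#' @param img Array or matrix of 0-255 intensities.
#' @return Same shape, values in `[0, 1]`.
#' @export
normalize_image <- function(img) {
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  img / 255
}

#' Power-law feature amplification
#'
#' Raises each normalised value to `exponent`.  For exponents below 1 dark
#' tones are pushed toward 0 and light tones toward 1 while relative
#' ordering is preserved, which deepens the contrast between furrows and
#' the surrounding skin plateau; 0 and 1 are fixed points.
#'
#' @param img Array or matrix of values in `[0, 1]`.
#' @param exponent Positive exponent (default 0.25).
#' @return Same shape, values in `[0, 1]`.
#' @export
amplify <- function(img, exponent = 0.25) {
  if (!is.numeric(exponent) || exponent <= 0)
    stop("`exponent` must be > 0", call. = FALSE)
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1)
    stop("amplification expects values in [0, 1]", call. = FALSE)
  img^exponent
}

#' Inverted binary threshold
#'
#' Maps gray values at or below `threshold` to wrinkle foreground and
#' values above it to background.  A value exactly at the threshold is
#' foreground: "above the threshold" means strictly above.
#'
#' @param gray H x W numeric matrix of gray values in 0-255.
#' @param threshold Cutoff in 0-255 (default 180).
#' @return Logical H x W matrix, `TRUE` = wrinkle foreground.
#' @export
binary_threshold_inv <- function(gray, threshold = 180) {
  if (!is.matrix(gray))
    stop("`gray` must be an H x W matrix", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 255)
    stop("`threshold` must lie in [0, 255]", call. = FALSE)
  rng <- range(gray)
  if (rng[1] < 0 || rng[2] > 255)
    stop("gray values must lie in [0, 255]", call. = FALSE)
  gray <= threshold
}

#' Segment wrinkles in a dermatoscope image
#'
#' Runs the full five-stage pipeline: Gaussian blur of the RGB frame,
#' normalisation to `[0, 1]`, per-channel power-law amplification,
#' grayscale conversion of the amplified image, rescaling to 0-255 and
#' inverted binary threshold.  The segmentation deliberately over-covers:
#' it marks not only the deep, dark core of each furrow but also the
#' shallower shoulders up to the skin plateau.  Thin hair strokes, whose
#' blurred contrast stays well above the amplified threshold, are not
#' segmented.
#'
#' For a uniform image of gray value v the mask is all-foreground iff
#' `255 * (v/255)^0.25 <= 180`, i.e. v <= 63 (empty for v >= 64) at the
#' default configuration.
#'
#' @param img An H x W x 3 array of 0-255 intensities.
#' @param config A [segmentation_config()].
#' @return Logical H x W matrix, `TRUE` = wrinkle foreground.
#' @examples
#' img <- array(30, dim = c(8, 8, 3))
#' sum(segment_wrinkles(img))  # 64: a uniformly dark frame is all wrinkle
#' @export
segment_wrinkles <- function(img, config = segmentation_config()) {
  validate_rgb(img)
  stopifnot(inherits(config, "segmentation_config"))
  blurred <- gaussian_blur(img, config$blur_kernel, config$sigma)
  normed <- normalize_image(blurred)
  amped <- amplify(normed, config$amplification_exponent)
  # grayscale of the amplified image, back on the 0-255 scale; kept
  # unrounded so the threshold decision is not perturbed by quantisation
  gray <- 255 * (0.299 * amped[, , 1L] + 0.587 * amped[, , 2L] +
                   0.114 * amped[, , 3L])
  binary_threshold_inv(gray, config$threshold)
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_logical_mask(a); b <- as_logical_mask(b)
  if (!identical(dim(a), dim(b)))
    stop("masks must have identical dimensions", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
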