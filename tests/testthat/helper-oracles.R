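# Naive reference implementations used as independent oracles.  They are
# deliberately written as explicit per-pixel loops with direct
# Gaussian-weight summation, sharing no code path with the package's
# separable/vectorised implementations.

# reflect-101 index for a scalar position (may lie outside 1..n)
ref101 <- function(i, n) {
  if (n == 1L) return(1L)
  m <- n - 1L
  j <- (i - 1L) %% (2L * m)
  if (j > m) j <- 2L * m - j
  j + 1L
}

# direct 2D convolution of one plane with the outer product of the 1D
# Gaussian kernel, explicit loop over output pixels
naive_blur_plane <- function(x, kernel, sigma = NULL) {
  k1 <- dermarough::gaussian_kernel_1d(kernel, sigma)
  k2 <- outer(k1, k1)
  half <- (kernel - 1L) / 2L
  H <- nrow(x); W <- ncol(x)
  ridx <- vapply(seq.int(1L - half, H + half), ref101, integer(1), n = H)
  cidx <- vapply(seq.int(1L - half, W + half), ref101, integer(1), n = W)
  xp <- x[ridx, cidx, drop = FALSE]
  out <- matrix(0, H, W)
  for (r in seq_len(H))
    for (c in seq_len(W))
      out[r, c] <- sum(k2 * xp[r:(r + kernel - 1L), c:(c + kernel - 1L)])
  out
}

# full pipeline, scalar per-pixel arithmetic after the naive blur;
# returns the pre-threshold 0-255 gray and the mask
naive_segment <- function(img, config = dermarough::segmentation_config()) {
  H <- dim(img)[1]; W <- dim(img)[2]
  blurred <- array(0, dim(img))
  for (ch in 1:3)
    blurred[, , ch] <- naive_blur_plane(img[, , ch], config$blur_kernel,
                                        config$sigma)
  gray <- matrix(0, H, W)
  wts <- c(0.299, 0.587, 0.114)
  for (r in seq_len(H))
    for (c in seq_len(W)) {
      acc <- 0
      for (ch in 1:3)
        acc <- acc + wts[ch] * (blurred[r, c, ch] / 255)^
          config$amplification_exponent
      gray[r, c] <- 255 * acc
    }
  list(gray = gray, mask = gray <= config$threshold)
}

# double-loop scalar evaluation of the roughness statistics
naive_roughness <- function(gray, mask, pixel_area = 0.203e-4,
                            take_sqrt = TRUE) {
  H <- nrow(gray); W <- ncol(gray)
  s <- 0; s2 <- 0; n_fg <- 0L
  for (r in seq_len(H))
    for (c in seq_len(W))
      if (mask[r, c]) {
        s <- s + gray[r, c]
        s2 <- s2 + gray[r, c]^2
        n_fg <- n_fg + 1L
      }
  ra <- s / (H * W)
  msq <- s2 / (H * W)
  list(ra = ra, rq = if (take_sqrt) sqrt(msq) else msq,
       wa = n_fg * pixel_area, count = n_fg)
}

# 8-connected component count via flood fill (for ground-truth topology)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  H <- nrow(mask); W <- ncol(mask)
  n <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    n <- n + 1L
    queue <- start
    lab[start] <- n
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r0 <- (p - 1L) %% H + 1L; c0 <- (p - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- r0 + dr; c <- c0 + dc
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- n
          queue <- c(queue, (c - 1L) * H + r)
        }
      }
    }
  }
  n
}

# small random RGB frame of 0-255 integers
random_rgb <- function(H, W, seed) {
  set.seed(seed)
  array(sample(0:255, H * W * 3, replace = TRUE), dim = c(H, W, 3L))
}

uniform_rgb <- function(v, H = 8L, W = 10L) array(v, dim = c(H, W, 3L))
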