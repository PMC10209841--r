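test_that("Gaussian blur preserves constants and kernel 1 is the identity", {
  img <- uniform_rgb(137, 20, 25)
  expect_equal(gaussian_blur(img, 37), img * 1.0)
  rnd <- random_rgb(15, 18, seed = 5)
  expect_equal(gaussian_blur(rnd, 1), rnd * 1.0)
  expect_error(gaussian_blur(rnd, 4), "odd")
  expect_error(gaussian_blur(rnd, -3), "odd")
})

test_that("blur of a point source spreads mass and matches direct convolution", {
  plane <- matrix(0, 25, 25); plane[13, 13] <- 255
  img <- array(plane, dim = c(25, 25, 3))
  b <- gaussian_blur(img, 9, sigma = 2)[, , 1]
  expect_lt(b[13, 13], 255)                 # centre strictly decreased
  expect_equal(sum(b), 255, tolerance = 1e-9)  # mass conserved away from borders
  # direct 2D-summation oracle, including reflect-101 border handling
  expect_equal(b, naive_blur_plane(plane, 9, sigma = 2), tolerance = 1e-9)
  set.seed(8)
  small <- matrix(sample(0:255, 12 * 10, replace = TRUE), 12, 10)
  expect_equal(gaussian_blur(array(small, c(12, 10, 3)), 7)[, , 1],
               naive_blur_plane(small, 7), tolerance = 1e-9)
})

test_that("normalisation and amplification obey their closed forms", {
  expect_equal(normalize_image(uniform_rgb(255))[1, 1, 1], 1)
  expect_equal(normalize_image(uniform_rgb(0))[1, 1, 1], 0)
  expect_equal(normalize_image(uniform_rgb(51))[1, 1, 1], 0.2)
  expect_error(normalize_image(uniform_rgb(0) - 5), "\\[0, 255\\]")

  x <- array(c(0, 1, 0.0625, 0.5), dim = c(1, 4, 1))[, , 1, drop = TRUE]
  expect_equal(amplify(matrix(c(0, 1), 1), 0.25), matrix(c(0, 1), 1))
  expect_equal(amplify(matrix(0.0625, 1), 0.25)[1, 1], 0.5)  # (1/16)^(1/4)
  m <- matrix(seq(0, 1, length.out = 11), 1)
  expect_equal(amplify(m, 1), m)
  expect_error(amplify(m, 0), "> 0")
  expect_error(amplify(m * 2, 0.25), "\\[0, 1\\]")
  # order preservation for exponent < 1
  expect_true(all(diff(amplify(m, 0.25)[1, ]) > 0))
})

test_that("inverted threshold assigns ties to foreground", {
  g <- matrix(c(179, 180, 181), 1)
  expect_identical(binary_threshold_inv(g, 180)[1, ],
                   c(TRUE, TRUE, FALSE))
  expect_error(binary_threshold_inv(g, 300), "\\[0, 255\\]")
})

test_that("uniform frames flip from full to empty mask between 63 and 64", {
  # analytic inversion: 255 * (v/255)^0.25 <= 180  <=>  v <= 63.46
  expect_true(all(segment_wrinkles(uniform_rgb(63))))
  expect_false(any(segment_wrinkles(uniform_rgb(64))))
  expect_false(any(segment_wrinkles(uniform_rgb(200))))
  expect_true(all(segment_wrinkles(uniform_rgb(30))))
})

test_that("segmentation is deterministic", {
  img <- random_rgb(40, 50, seed = 9)
  expect_identical(segment_wrinkles(img), segment_wrinkles(img))
})

test_that("composed pipeline matches the naive per-pixel reference", {
  cfg <- segmentation_config(blur_kernel = 7)
  for (s in 1:6) {
    img <- random_rgb(16 + s, 20, seed = 100 + s)
    ref <- naive_segment(img, cfg)
    blurred <- gaussian_blur(img, cfg$blur_kernel, cfg$sigma)
    amped <- amplify(normalize_image(blurred), cfg$amplification_exponent)
    gray <- 255 * (0.299 * amped[, , 1] + 0.587 * amped[, , 2] +
                     0.114 * amped[, , 3])
    expect_lt(max(abs(gray - ref$gray)), 1)
    mask <- segment_wrinkles(img, cfg)
    clear <- abs(ref$gray - cfg$threshold) > 1   # away from border-effect ties
    expect_identical(mask[clear], ref$mask[clear])
  }
})

test_that("darkening pixels can only add mask pixels (antitone inclusion)", {
  set.seed(21)
  for (rep in 1:15) {
    img <- random_rgb(24, 30, seed = 300 + rep)
    m0 <- segment_wrinkles(img, segmentation_config(blur_kernel = 9))
    r <- sample(1:18, 1); c <- sample(1:22, 1)
    img2 <- img
    img2[r:(r + 5), c:(c + 5), ] <-
      pmax(img2[r:(r + 5), c:(c + 5), ] - sample(20:120, 1), 0)
    m1 <- segment_wrinkles(img2, segmentation_config(blur_kernel = 9))
    expect_true(all(m1[m0]))   # m1 is a superset of m0
  }
})

test_that("a step-edge furrow is segmented including its blurred edges", {
  # wide vertical dark band on a light plateau: the mask must cover the
  # deep core of the furrow entirely, extend beyond it onto the blurred
  # shoulders, and leave the distant plateau clear
  plane <- matrix(170, 60, 90)
  band <- 31:60                 # the furrow
  core <- 41:50                 # its deep core
  plane[, band] <- 40
  img <- array(plane, dim = c(60, 90, 3))
  mask <- segment_wrinkles(img)
  expect_true(all(mask[, core]))
  expect_gt(sum(mask), length(core) * 60)   # strictly wider than the core
  expect_false(any(mask[, c(1:10, 81:90)])) # plateau far away stays clear
})

test_that("segmentation_config validates its fields", {
  expect_error(segmentation_config(blur_kernel = 36), "odd")
  expect_error(segmentation_config(amplification_exponent = -1), "> 0")
  expect_error(segmentation_config(threshold = 256), "\\[0, 255\\]")
  expect_equal(dermarough:::gaussian_sigma(segmentation_config()),
               0.3 * (18 - 1) + 0.8)
})
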