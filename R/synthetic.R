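# Synthetic dermatoscope frames with known ground truth.
#
# A frame is a light skin plateau (background_gray) carrying additive
# Gaussian texture noise, crossed by dark curvilinear furrows and,
# optionally, thin dark hair strokes.  Each furrow is a sinusoidal path
# with a flat dark core of the drawn width and Gaussian shoulders of
# spread wrinkle_sigma_px; its ground-truth mask is the half-depth contour
# of the darkening profile (core + sigma * sqrt(2 ln 2) on each side).
# Hairs are straight, constant-width, shallower strokes and are *not* part
# of the ground truth: the segmentation pipeline is expected to reject
# them.  Furrow paths are laid out in separated horizontal lanes so that
# ground-truth components are disjoint by construction.
#
# All stochastic quantities are drawn as unit uniform/normal variates
# before being mapped through the spec parameters, so two specs differing
# only in darkness/width share identical geometry and noise under the same
# seed.

#' Specification of a synthetic dermatoscope frame
#'
#' Defaults give a high-contrast, clearly-resolvable frame at the reduced
#' test resolution 400 x 300: background tone 170, furrow darkness 120
#' (core tone 50), core widths 16-24 px with 5 px Gaussian shoulders, two
#' faint thin hairs, and texture noise of sd 4 gray levels.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param background_gray Skin plateau tone in 0-255.
#' @param n_wrinkles Number of furrows (laid out in separated lanes).
#' @param wrinkle_width_px Length-2 range (or scalar) of furrow core
#'   widths in px.
#' @param wrinkle_darkness Gray-level depression at the furrow core, so
#'   core tone = `background_gray - wrinkle_darkness` (must stay >= 0).
#' @param wrinkle_sigma_px Gaussian spread of the furrow shoulders in px.
#' @param n_hairs Number of thin straight hair strokes.
#' @param hair_width_px Hair stroke width in px (<= 2 recommended).
#' @param hair_darkness Gray-level depression of hair strokes.
#' @param noise_sd Additive Gaussian texture noise sd in gray levels.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width_px = 400L, height_px = 300L,
                           background_gray = 170,
                           n_wrinkles = 4L,
                           wrinkle_width_px = c(16, 24),
                           wrinkle_darkness = 120,
                           wrinkle_sigma_px = 5,
                           n_hairs = 2L,
                           hair_width_px = 2,
                           hair_darkness = 60,
                           noise_sd = 4,
                           seed = 1L) {
  if (length(wrinkle_width_px) == 1L)
    wrinkle_width_px <- rep(wrinkle_width_px, 2L)
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               background_gray = background_gray,
               n_wrinkles = as.integer(n_wrinkles),
               wrinkle_width_px = as.numeric(wrinkle_width_px),
               wrinkle_darkness = wrinkle_darkness,
               wrinkle_sigma_px = wrinkle_sigma_px,
               n_hairs = as.integer(n_hairs),
               hair_width_px = hair_width_px,
               hair_darkness = hair_darkness,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(s) {
  if (s$width_px < 1L || s$height_px < 1L)
    stop("frame dimensions must be >= 1", call. = FALSE)
  if (s$background_gray < 0 || s$background_gray > 255)
    stop("`background_gray` must lie in [0, 255]", call. = FALSE)
  if (s$background_gray - s$wrinkle_darkness < 0)
    stop("`wrinkle_darkness` may not exceed `background_gray`", call. = FALSE)
  if (s$n_wrinkles < 0L || s$n_hairs < 0L)
    stop("counts must be >= 0", call. = FALSE)
  if (s$n_wrinkles > 0L && any(s$wrinkle_width_px < 1))
    stop("wrinkle widths must be >= 1 px", call. = FALSE)
  if (s$n_hairs > 0L && s$hair_width_px < 1)
    stop("`hair_width_px` must be >= 1", call. = FALSE)
  if (any(s$wrinkle_darkness < 0, s$hair_darkness < 0, s$noise_sd < 0,
          s$wrinkle_sigma_px < 0))
    stop("darkness, noise and sigma must be >= 0", call. = FALSE)
  invisible(s)
}

# run `expr` under a seeded RNG without disturbing the caller's RNG state
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# half-width of the half-depth contour for a flat core + Gaussian shoulder
truth_halfwidth <- function(width, sigma) {
  width / 2 + sigma * sqrt(2 * log(2))
}

#' Generate a synthetic dermatoscope frame with ground truth
#'
#' Renders the frame described by `spec` and the exact ground-truth
#' wrinkle mask (half-depth contour of each furrow's darkening profile;
#' hairs excluded).  Deterministic under the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `image` (H x W x 3 array, 0-255), `mask` (logical
#'   H x W ground truth, hairs excluded), `hair_mask` (logical H x W, the
#'   hair strokes), `depth` (the noise-free darkening field) and `spec`.
#' @examples
#' frame <- generate_image(synthetic_spec(width_px = 120, height_px = 90,
#'                                        n_wrinkles = 2, seed = 7))
#' mean(frame$mask)
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng(spec$seed, render_frame(spec))
}

render_frame <- function(s) {
  H <- s$height_px; W <- s$width_px
  depth <- matrix(0, H, W)
  truth <- matrix(FALSE, H, W)

  if (s$n_wrinkles > 0L) {
    # unit draws first: geometry is invariant to darkness/width rescaling
    u_width <- stats::runif(s$n_wrinkles)
    u_freq  <- stats::runif(s$n_wrinkles)
    u_phase <- stats::runif(s$n_wrinkles)
    u_amp   <- stats::runif(s$n_wrinkles)
    u_jit   <- stats::runif(s$n_wrinkles, -1, 1)

    widths <- s$wrinkle_width_px[1] +
      u_width * diff(s$wrinkle_width_px)
    reach <- truth_halfwidth(max(widths), s$wrinkle_sigma_px)
    lane_h <- H / s$n_wrinkles
    if (lane_h < 2 * reach + 2)
      stop(sprintf(
        "cannot place %d non-overlapping wrinkles of reach %.1f px in %d rows",
        s$n_wrinkles, reach, H), call. = FALSE)

    for (i in seq_len(s$n_wrinkles)) {
      if (s$wrinkle_darkness <= 0 || widths[i] <= 0) next
      centre <- (i - 0.5) * lane_h + u_jit[i] * (lane_h / 2 - reach - 1) * 0.5
      slack <- lane_h / 2 - reach - 1 - abs(centre - (i - 0.5) * lane_h)
      amp <- u_amp[i] * max(slack, 0)
      freq <- 0.5 + u_freq[i]                      # 0.5-1.5 periods across W
      phase <- u_phase[i] * 2 * pi
      xs <- seq_len(W)
      ys <- centre + amp * sin(2 * pi * freq * (xs - 1) / max(W - 1, 1) + phase)
      d <- path_distance(H, W, ys,
                         window = ceiling(truth_halfwidth(widths[i],
                                                          s$wrinkle_sigma_px)) + 2L)
      prof <- furrow_profile(d, widths[i], s$wrinkle_sigma_px)
      depth <- pmax(depth, s$wrinkle_darkness * prof)
      truth <- truth | (d <= truth_halfwidth(widths[i], s$wrinkle_sigma_px))
    }
  }

  hair <- matrix(FALSE, H, W)
  if (s$n_hairs > 0L) {
    u_x0  <- stats::runif(s$n_hairs)
    u_y0  <- stats::runif(s$n_hairs)
    u_ang <- stats::runif(s$n_hairs)
    for (i in seq_len(s$n_hairs)) {
      if (s$hair_darkness <= 0) next
      hd <- hair_stroke_depth(H, W,
                              x0 = 1 + u_x0[i] * (W - 1),
                              y0 = 1 + u_y0[i] * (H - 1),
                              angle = u_ang[i] * pi,
                              width = s$hair_width_px,
                              darkness = s$hair_darkness)
      hair <- hair | (hd > 0)
      depth <- pmax(depth, hd)
    }
  }

  noise <- if (s$noise_sd > 0)
    matrix(stats::rnorm(H * W, 0, s$noise_sd), H, W) else 0
  gray <- pmin(pmax(round(s$background_gray - depth + noise), 0), 255)
  list(image = array(gray, dim = c(H, W, 3L)), mask = truth,
       hair_mask = hair, depth = depth, spec = s)
}

# distance from every pixel to the path {(ys[c], c)}, exact within `window`
# columns of each pixel (Inf beyond; ample for profiles that decay to 0)
path_distance <- function(H, W, ys, window) {
  D <- matrix(Inf, H, W)
  rows <- matrix(seq_len(H), H, W)
  for (off in (-window):window) {
    src <- seq_len(W) + off
    ok <- src >= 1L & src <= W
    if (!any(ok)) next
    yrow <- rep(NA_real_, W)
    yrow[ok] <- ys[src[ok]]
    cand <- sqrt((rows - matrix(yrow, H, W, byrow = TRUE))^2 + off^2)
    cand[is.na(cand)] <- Inf
    D <- pmin(D, cand)
  }
  D
}

# flat core of the given width, Gaussian shoulders beyond it
furrow_profile <- function(d, width, sigma) {
  excess <- pmax(d - width / 2, 0)
  if (sigma > 0) exp(-excess^2 / (2 * sigma^2)) else as.numeric(excess == 0)
}

# constant-width straight stroke through (x0, y0) at `angle`, hard edges
hair_stroke_depth <- function(H, W, x0, y0, angle, width, darkness) {
  dx <- cos(angle); dy <- sin(angle)
  len <- sqrt(H^2 + W^2)
  t <- seq(-len, len, by = 0.5)
  px <- x0 + t * dx; py <- y0 + t * dy
  keep <- px >= -width & px <= W + width & py >= -width & py <= H + width
  px <- px[keep]; py <- py[keep]
  depth <- matrix(0, H, W)
  r <- ceiling(width / 2) + 1L
  half <- width / 2
  for (k in seq_along(px)) {
    rr <- max(1L, floor(py[k]) - r):min(H, ceiling(py[k]) + r)
    cc <- max(1L, floor(px[k]) - r):min(W, ceiling(px[k]) + r)
    if (!length(rr) || !length(cc)) next
    dd <- sqrt(outer((rr - py[k])^2, (cc - px[k])^2, `+`))
    depth[rr, cc] <- pmax(depth[rr, cc], darkness * (dd <= half))
  }
  depth
}

#' Specification of a paired two-timepoint cohort
#'
#' Describes a cosmetic-efficacy style study: each subject is imaged at
#' baseline (D0) and again after treatment (D45), with the treatment
#' shrinking furrow darkness and width by `effect_fraction`.
#'
#' @param n_subjects Number of subjects (>= 2; 33 in a typical study arm).
#' @param effect_fraction Multiplicative reduction of wrinkle darkness and
#'   width at D45, in `[0, 1]`; 0 = null treatment, 1 = wrinkles gone.
#' @param between_subject_sd SD of the multiplicative between-subject
#'   factor applied to darkness and width (lognormal-style, truncated
#'   below at 0.2).
#' @param seed RNG seed for subject-level draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 33L, effect_fraction = 0.5,
                        between_subject_sd = 0.15, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L)
    stop("`n_subjects` must be >= 2", call. = FALSE)
  if (effect_fraction < 0 || effect_fraction > 1)
    stop("`effect_fraction` must lie in [0, 1]", call. = FALSE)
  if (between_subject_sd < 0)
    stop("`between_subject_sd` must be >= 0", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 effect_fraction = effect_fraction,
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a paired D0/D45 cohort of synthetic frames
#'
#' For each subject, draws a between-subject factor scaling furrow
#' darkness and width, renders the baseline (D0) frame, then renders the
#' post-treatment (D45) frame with darkness and width multiplied by
#' `1 - effect_fraction` while keeping the same furrow geometry and noise
#' (same per-subject seed).  With `analyze = TRUE` each frame is run
#' through [analyze_image()] and the roughness statistics are attached; a
#' `reference` column carries the ground-truth mean darkening of the
#' frame, playing the role of a gold-standard depth-based instrument.
#'
#' @param img_spec A [synthetic_spec()] giving the population-level frame
#'   parameters.
#' @param cohort A [cohort_spec()].
#' @param analyze Run segmentation + roughness on every frame (default
#'   `TRUE`).
#' @param config,geometry Passed to [analyze_image()].
#' @param keep_images Retain the rendered frames in a list column
#'   (default `FALSE`; frames are large).
#' @return A data.frame with one row per subject per timepoint: columns
#'   `subject_id`, `timepoint` ("D0"/"D45"), `darkness`, `width_lo`,
#'   `width_hi`, `reference`, and — when `analyze = TRUE` —
#'   `wrinkle_pixel_count`, `ra`, `rq`, `wa`.
#' @export
generate_cohort <- function(img_spec, cohort, analyze = TRUE,
                            config = segmentation_config(),
                            geometry = device_geometry(),
                            keep_images = FALSE) {
  stopifnot(inherits(img_spec, "synthetic_spec"),
            inherits(cohort, "cohort_spec"))
  draws <- with_rng(cohort$seed, list(
    factor = pmax(0.2, 1 + stats::rnorm(cohort$n_subjects, 0,
                                        cohort$between_subject_sd)),
    seeds = sample.int(2^31 - 2, cohort$n_subjects)
  ))
  rows <- vector("list", 2L * cohort$n_subjects)
  images <- if (keep_images) vector("list", 2L * cohort$n_subjects)
  k <- 0L
  for (i in seq_len(cohort$n_subjects)) {
    for (tp in c("D0", "D45")) {
      scale_tp <- if (tp == "D0") 1 else 1 - cohort$effect_fraction
      sc <- draws$factor[i] * scale_tp
      darkness <- min(img_spec$wrinkle_darkness * sc, img_spec$background_gray)
      widths <- pmax(img_spec$wrinkle_width_px * sc, 0)
      sub_spec <- img_spec
      sub_spec$wrinkle_darkness <- darkness
      sub_spec$wrinkle_width_px <- widths
      sub_spec$seed <- draws$seeds[i]
      if (darkness <= 0 || all(widths < 1)) sub_spec$n_wrinkles <- 0L
      sub_spec <- structure(sub_spec, class = "synthetic_spec")
      frame <- generate_image(sub_spec)
      row <- data.frame(subject_id = i, timepoint = tp,
                        darkness = darkness,
                        width_lo = widths[1], width_hi = widths[2],
                        reference = mean(frame$depth))
      if (analyze) {
        res <- analyze_image(frame$image, config = config,
                             geometry = geometry)
        row <- cbind(row, as.data.frame(res)[
          c("wrinkle_pixel_count", "ra", "rq", "wa")])
      }
      k <- k + 1L
      rows[[k]] <- row
      if (keep_images) images[[k]] <- frame
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_images) attr(out, "frames") <- images
  out
}

#' Reshape a cohort into the paired-measurement table used by the
#' statistics workflow
#'
#' @param cohort_df Output of [generate_cohort()] (long format, one row
#'   per subject per timepoint).
#' @param parameters Which measurement columns to extract.
#' @return A data.frame with columns `subject_id`, `parameter`, `d0`,
#'   `d45` — one row per subject per parameter.
#' @export
cohort_table <- function(cohort_df,
                         parameters = intersect(
                           c("ra", "rq", "wa", "reference"),
                           names(cohort_df))) {
  stopifnot(all(c("subject_id", "timepoint") %in% names(cohort_df)),
            length(parameters) > 0,
            all(parameters %in% names(cohort_df)))
  d0 <- cohort_df[cohort_df$timepoint == "D0", , drop = FALSE]
  d45 <- cohort_df[cohort_df$timepoint == "D45", , drop = FALSE]
  d0 <- d0[order(d0$subject_id), , drop = FALSE]
  d45 <- d45[order(d45$subject_id), , drop = FALSE]
  if (!identical(d0$subject_id, d45$subject_id))
    stop("cohort is not fully paired: D0 and D45 subject ids differ",
         call. = FALSE)
  out <- do.call(rbind, lapply(parameters, function(p) {
    data.frame(subject_id = d0$subject_id, parameter = p,
               d0 = d0[[p]], d45 = d45[[p]])
  }))
  rownames(out) <- NULL
  out
}
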