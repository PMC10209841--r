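---
title: "Wrinkle segmentation and image-based roughness: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrinkle segmentation and image-based roughness: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermarough)
```

## The measurement problem

A USB dermatoscope images a few square millimetres of skin (reference
geometry: 1600 × 1200 px over 7 × 6.5 mm) under coaxial LED light. Furrows
and wrinkles sit farther from the illuminator and lens, return less light,
and appear as dark curvilinear valleys on a lighter plateau. A 2-D frame
carries no depth in micrometers, so the package's roughness statistics are
*image-based*: they quantify how much dark wrinkle mass a frame contains,
in gray levels and mm², and are meaningful for within-device comparisons
(before vs after treatment, subject vs subject) and for rank correlation
against a depth-based instrument — not for absolute comparison with
profilometric roughness in µm.

## The segmentation pipeline and its assumptions

`segment_wrinkles()` chains five deterministic stages:

| stage | operation | default | purpose |
|---|---|---|---|
| 1 | Gaussian blur | 37 × 37 kernel, σ ≈ 5.9 px | homogenise illumination, kill small artifacts |
| 2 | normalise | ÷ 255 | put all channels on [0, 1] |
| 3 | amplify | x ↦ x^0.25 | deepen furrow contrast, suppress hairs |
| 4 | grayscale | Rec.601 luma, × 255 | single channel for thresholding |
| 5 | inverted threshold | foreground ≤ 180 | binary wrinkle mask |

Assumptions: wrinkles are *darker* than their surroundings (shadow-based
contrast); illumination is roughly uniform after the blur; frames are
8-bit per channel. The pipeline has no morphological post-processing —
none is part of the method — so isolated dark speckles that survive the
blur will appear in the mask.

Every stage is monotone in pixel intensity and the final threshold is
order-reversing, which yields the pipeline's key invariant: **darkening
any pixel can only add mask pixels, never remove any**. The test suite
asserts this *antitone inclusion* property on randomized patches, and the
closed form it implies on uniform frames: a constant-v image is
all-foreground iff `255·(v/255)^0.25 ≤ 180`, i.e. v ≤ 63 (empty from 64
up), since the blur preserves constants.

### Tunable parameters

* `blur_kernel` (px, default 37): sized for 1600 × 1200 frames; on
  heavily downscaled images it blurs proportionally more, which the
  synthetic tests exploit deliberately (wide furrows at 400 × 300).
* `amplification_exponent` (dimensionless, default 0.25): the operating
  point at which thin hairs stop being segmented while furrows deepen;
  exponent 1 disables amplification.
* `threshold` (gray levels, default 180): applied to the amplified
  grayscale; through the amplification it corresponds to original gray
  ≈ 63 on neutral input.
* `sigma` (px, default derived): the blur σ is not part of the stated
  method, only the kernel size is; we adopt the convention of mainstream
  vision libraries, σ = 0.3·((k−1)/2 − 1) + 0.8, so that results track
  implementations built on those libraries. It is configurable for
  sensitivity analysis.

### Numerical choices

* **Border handling**: reflect-101 padding (mirror about the edge pixel
  without repeating it), again the mainstream-library default. With a
  37-px kernel, borders are material on small test frames; the oracle
  tests reproduce the identical rule in a naive direct convolution.
* **Rescale point**: amplification operates on [0, 1] but the threshold
  is stated on 0–255; the amplified grayscale is multiplied by 255
  immediately before thresholding — the only ordering under which the
  printed threshold is meaningful.
* **Stage order**: amplification is per channel on the normalised RGB
  image; the grayscale is computed *after* amplification.
* **Threshold tie**: a value exactly at the threshold is foreground
  ("above the threshold" is strict).
* **Quantisation**: the pre-threshold grayscale is kept as floating
  point; rounding it first could flip pixels within half a gray level of
  the cutoff. `to_grayscale()` (used for the roughness statistics, where
  8-bit semantics are wanted) rounds half-to-even.

## Roughness statistics

With G the grayscale of the *original* frame (never the amplified one),
W the predicted mask, and w × h the frame size:

* `average_roughness()` — Ra = Σ Wp(G) / (w·h). The denominator is the
  **total** pixel count, not the foreground count. This is deliberate and
  differs from classical Ra: the statistic responds both to how dark and
  to how extensive the wrinkles are, and equals 0 for a wrinkle-free
  frame.
* `rms_roughness()` — the quadratic analogue. The quantity is named
  root-mean-square, and the default applies the square root,
  Rq = √(Σ Wp(G)² / wh); conventions that omit the radical are available
  via `take_sqrt = FALSE`. With the root, Rq ≥ Ra always
  (Cauchy–Schwarz), which is asserted as a property test.
* `wrinkle_area()` — Wa = |W| × pixel area. The default per-pixel area,
  0.203·10⁻⁴ mm², is the device calibration constant and is *not* equal
  to the field-of-view quotient 7 × 6.5 / (1600·1200) = 2.37·10⁻⁵ mm²;
  the constant is kept verbatim so Wa matches values reported for this
  device class, and the discrepancy is documented in
  `?device_geometry`. Non-default optics require an explicit
  `pixel_area_mm2`.

## What the synthetic generator emulates — and what it does not

`generate_image()` renders: a uniform skin plateau (default tone 170)
with additive Gaussian texture noise (sd 4, clipped to [0, 255]); dark
furrows as sinusoidal curvilinear paths with a flat core (width drawn
from 16–24 px at the 400 × 300 test geometry) and Gaussian shoulders
(σ = 5 px), depressed by 120 gray levels at the core; and optional thin
hair strokes (width 2 px, depression 60) with hard edges. Ground truth is
the half-depth contour of each furrow's darkening profile — an
unambiguous, resolution-independent definition suited to Dice scoring.
Furrows are laid out in separated horizontal lanes, so ground-truth
components are disjoint by construction (the generator refuses
configurations that cannot fit).

The default contrast regime was chosen *analytically before any test was
run*: a 1-D convolution estimate shows a 16-px-wide, 120-deep furrow
under the σ ≈ 5.9 blur keeps a blurred core near gray 53, safely below
the detection bound of 63.5, while a 2-px, 60-deep hair blurs to ≈ 162
and can never be segmented. The generator draws all stochastic quantities
as unit variates before mapping them through the spec parameters, so
frames that differ only in darkness/width share geometry and noise under
one seed — this is what makes the monotone dose–response test exact and
lets a treated (D45) frame reuse its baseline (D0) geometry.

Not emulated: photorealistic skin texture and pores, chromatic variation
(frames are neutral gray in all three channels), specular highlights,
curved-surface vignetting, or any quantitative match to real wrinkle
contrast distributions, which are not characterised in the source
material. A green Dice test therefore establishes that the pipeline's
*contracts* hold in a stated high-contrast regime — over-coverage of
shoulders, hair rejection at the stated width/contrast, monotone dose
response — not clinical segmentation accuracy.

`generate_cohort()` adds a truncated-normal multiplicative
between-subject factor (sd 0.15) on furrow darkness and width, and
models treatment as scaling both by `1 − effect_fraction` at D45. Two
consequences worth knowing: with `effect_fraction = 0` the D45 frame is
*identical* to D0 (the null cohort is exactly degenerate, by design);
and at `effect_fraction = 0.5` the halved darkness (≈ 60) falls below
the uniform-detection bound, so D45 masks are typically empty and the
Wa decrease is detected with near-certainty. The latter is a property of
this stated world, not a calibration: treatment effects between ~0.1 and
~0.3 produce graded responses.

## Statistical workflow

`paired_compare()` mirrors standard efficacy-study practice: Shapiro–Wilk
on each timepoint's sample; both p ≥ α ⇒ two-sided paired t-test, else
two-sided Wilcoxon signed-rank (normal approximation; zero differences
discarded in the classical manner, with the zero fraction reported). A
constant sample has no Shapiro–Wilk p-value; it is returned as `NA` and
gates to the non-parametric branch. If *every* difference is zero the
comparison is degenerate: no test is run and `significant` is `FALSE`.
All p-values are raw — the workflow applies no multiple-testing
correction, matching the convention of the studies it serves, and says so
in its output.

`spearman_correlation()` uses the asymptotic tie-safe p-value and bands
the *magnitude* of rs (the sign is reported separately, since the
conventional scale is stated for 0–1): 0–0.19 very weak, 0.2–0.39 weak,
0.4–0.69 moderate, 0.7–0.89 strong, 0.9–1 very strong. The intervals are
closed as printed; magnitudes are rounded to two decimals before lookup,
which resolves values between printed bounds (0.195 → 0.20 → weak). Test
sidedness is two-sided throughout — the source convention does not state
it, and two-sided is the conservative default.

## Known limitations

* No TIFF input: no TIFF decoder is available in the dependency
  footprint; PNG and JPEG are supported (16-bit PNGs are rescaled to
  8-bit on load). Convert TIFF frames to PNG upstream.
* Ra/Rq are gray-level statistics; they are not comparable in µm to
  profilometric roughness and should only be compared across images from
  the same device and lighting.
* The threshold of 180 presumes the stated amplification exponent and
  broadly neutral exposure; frames with very dark skin tones will exceed
  the uniform-detection bound everywhere and segment the whole frame
  (the closed form above tells you exactly when: mean tone ≤ 63).
* Hair rejection is demonstrated at the tested width/contrast (≤ 2 px,
  depression ≤ 60); thick or very dark hairs blur like furrows and will
  be segmented.
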