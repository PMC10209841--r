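Package: dermarough
Title: Wrinkle Segmentation and Skin Roughness Quantification from
    Dermatoscope Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects skin wrinkles in dermatoscope (USB digital microscope)
    images through a five-stage segmentation pipeline (Gaussian blur,
    normalisation, power-law feature amplification, grayscale conversion,
    inverted binary threshold) and quantifies skin surface roughness over
    the detected wrinkle regions: image-based average roughness (Ra),
    root-mean-square roughness (Rq) and wrinkle area (Wa).  Includes a
    synthetic dermatoscope-frame generator with ground-truth wrinkle masks
    and paired two-timepoint cohorts, and the statistical workflow used in
    cosmetic efficacy studies (Shapiro-Wilk normality gating, paired t-test
    or Wilcoxon signed-rank comparison, Spearman correlation with strength
    bands).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    png,
    jpeg,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
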