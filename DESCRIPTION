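Package: selfieplaque
Title: Dental Plaque Quantification from Smartphone Smile Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dental plaque from smartphone photographs of the smile.
    Tooth regions defined by binary masks are decomposed into hue, saturation and
    brightness channels; plaque pixels are selected by saturation thresholding
    (automatic Otsu or a fixed band) and summarised as the percent plaque-area
    fraction of the tooth area. Linear calibration models map the anterior-teeth
    fraction to full-mouth selfie plaque indices (SVPI for visible plaque, SDPI
    after disclosing dye), shipped with published coefficients and refittable by
    ordinary least squares. Clinical reference indices (visible plaque index of
    Ainamo and Bay, the O'Leary disclosed index) are computed from per-surface
    dichotomous records, full-mouth and anterior-only, and compared with the
    image-derived scores by Spearman rank correlation. A synthetic-data module
    generates smile-like images with known plaque fractions and cohort tables
    with controllable noise so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    jpeg,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
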