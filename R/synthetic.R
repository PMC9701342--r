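# Synthetic smiles and cohorts.
#
# The generator emulates the imaging conditions of the smile protocol at desk
# scale: a row of anterior teeth (low-saturation enamel) on a dark oral
# background, with plaque (high-saturation, dye-like colour) accreting along
# the cervical margin of each tooth — the location where plaque accumulates
# clinically — until a requested fraction of the tooth area is covered.
# Ground truth (mask, plaque raster, exact pixel fraction) is returned with
# the image, so the full pipeline is testable closed-loop. Everything is
# deterministic for a given seed; no hidden global RNG state leaks.

clamp_byte <- function(x) pmin(255, pmax(0, x))

#' Generate a synthetic smile image with known plaque fraction
#'
#' Draws `n_teeth` elliptical anterior teeth on a dark background and covers
#' a target percentage of the total tooth area with plaque-coloured pixels,
#' accreted from the cervical (gingival) edge of each tooth downward with a
#' jittered front. Per-channel Gaussian noise emulates smartphone capture.
#' The returned `true_fraction_pct` is the exact pixel-count ratio, within
#' 0.5 percentage points of the target (pixel quantisation).
#'
#' @param target_fraction_pct Requested plaque coverage, percent of tooth
#'   area, in `[0, 100]`.
#' @param width,height Image dimensions in pixels.
#' @param n_teeth Number of teeth (default 6: four incisors and two canines,
#'   the teeth visible in a natural smile).
#' @param tooth_color,plaque_color,background_color RGB byte triples. The
#'   defaults give low-saturation enamel and a strongly saturated plaque
#'   stain, separated by well over 100 saturation levels.
#' @param noise_sd Per-channel Gaussian noise standard deviation (byte units).
#' @param jitter Roughness of the plaque front, as a fraction of tooth height.
#' @param seed RNG seed; fixes all randomness in the call.
#' @return A `synthetic_smile` list: `image` ([smile_image()]), `mask`
#'   (logical tooth raster), `plaque` (logical ground-truth plaque raster,
#'   a subset of `mask`), `true_fraction_pct`, and `spec` (the arguments).
#' @examples
#' sm <- generate_smile(target_fraction_pct = 25, width = 160, height = 120,
#'                      seed = 1)
#' sm$true_fraction_pct
#' @export
generate_smile <- function(target_fraction_pct = 25,
                           width = 640, height = 480,
                           n_teeth = 6,
                           tooth_color = c(235, 228, 215),
                           plaque_color = c(186, 120, 36),
                           background_color = c(25, 28, 32),
                           noise_sd = 3,
                           jitter = 0.15,
                           seed = 1) {
  if (target_fraction_pct < 0 || target_fraction_pct > 100) {
    abort_input("`target_fraction_pct` must lie in [0, 100].")
  }
  if (width < 16 || height < 16) {
    abort_input("Image must be at least 16 x 16 pixels.")
  }
  withr::with_seed(seed, {
    xs <- matrix(rep(seq_len(width), each = height), nrow = height)
    ys <- matrix(rep(seq_len(height), times = width), nrow = height)
    mask <- matrix(FALSE, height, width)
    depth <- matrix(Inf, height, width)  # normalized depth below cervical edge
    # mild taper toward the canines
    taper <- 1 - 0.15 * abs(seq_len(n_teeth) - (n_teeth + 1) / 2) /
      ((n_teeth - 1) / 2 + 1e-9)
    for (i in seq_len(n_teeth)) {
      cx <- width * (0.05 + 0.9 * (i - 0.5) / n_teeth)
      rx <- 0.9 * width / (2 * n_teeth) * 0.85
      ry <- 0.28 * height * taper[i]
      cy <- 0.45 * height
      inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      mask <- mask | inside
      d <- (ys - (cy - ry)) / (2 * ry)
      depth[inside] <- pmin(depth[inside], d[inside])
    }
    ta <- sum(mask)
    k <- round(target_fraction_pct / 100 * ta)
    achievable <- 50 / ta  # max quantisation error, percentage points
    if (achievable > 0.5) {
      abort_input(sprintf(
        "Target fraction not reachable within 0.5 pp at this resolution (TA = %d px, best achievable %.2f pp); use a larger image.",
        ta, achievable))
    }
    plaque <- matrix(FALSE, height, width)
    if (k > 0) {
      idx <- which(mask)
      score <- depth[idx] + runif(length(idx), 0, jitter)
      plaque[idx[order(score)[seq_len(k)]]] <- TRUE
    }
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      plane <- matrix(background_color[ch], height, width)
      plane[mask] <- tooth_color[ch]
      plane[plaque] <- plaque_color[ch]
      if (noise_sd > 0) {
        plane <- plane + rnorm(length(plane), 0, noise_sd)
      }
      img[, , ch] <- round(clamp_byte(plane))
    }
    structure(
      list(image = smile_image(img), mask = mask, plaque = plaque,
           true_fraction_pct = 100 * k / ta,
           spec = list(target_fraction_pct = target_fraction_pct,
                       width = width, height = height, n_teeth = n_teeth,
                       tooth_color = tooth_color, plaque_color = plaque_color,
                       background_color = background_color,
                       noise_sd = noise_sd, jitter = jitter, seed = seed)),
      class = "synthetic_smile"
    )
  })
}

#' @export
print.synthetic_smile <- function(x, ...) {
  cat(sprintf(
    "<synthetic_smile> %d x %d, %d teeth, TA = %d px, true plaque %.2f%%\n",
    x$spec$width, x$spec$height, x$spec$n_teeth, total_area(x$mask),
    x$true_fraction_pct))
  invisible(x)
}

#' Write a synthetic smile to image and mask PNGs
#'
#' @param smile A `synthetic_smile`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; writes `<stem>.png`, `<stem>_mask.png` and
#'   `<stem>_plaque.png`.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_smile_fixture <- function(smile, dir, stem = "smile") {
  if (!inherits(smile, "synthetic_smile")) {
    abort_input("`smile` must come from `generate_smile()`.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(image = file.path(dir, paste0(stem, ".png")),
             mask = file.path(dir, paste0(stem, "_mask.png")),
             plaque = file.path(dir, paste0(stem, "_plaque.png")))
  write_smile_image(smile$image, paths["image"])
  write_tooth_mask(smile$mask, paths["mask"])
  write_tooth_mask(smile$plaque, paths["plaque"])
  invisible(paths)
}

#' Generate a synthetic calibration/validation cohort
#'
#' Emulates a clinical cohort for the selfie-index validation: each subject
#' gets an anterior plaque-area fraction drawn uniformly from
#' `fraction_range`; the generative truth for the full-mouth indices is the
#' calibration line evaluated at that fraction plus Gaussian noise, clamped
#' to the index scale. Per-surface dichotomous records (28 teeth x 4
#' surfaces, visible and disclosed) are sampled so that their computed index
#' matches each subject's index to the nearest achievable surface count, and
#' the anterior partial indices are computed from those records.
#'
#' @param n_subjects Number of subjects (default 47, a typical validation
#'   cohort size).
#' @param fraction_range Range of the uniform anterior-fraction distribution,
#'   percent.
#' @param index_noise_sd SD of the noise linking fraction to clinical index,
#'   index percent units.
#' @param calibration_visible,calibration_disclosed Generative
#'   `calibration_model`s (defaults: the published equations).
#' @param seed RNG seed; fixes all randomness.
#' @return A `synthetic_cohort` list: `subjects` (tibble with columns
#'   `subject_id`, `fraction_pct`, `VPI`, `DPI`, `SVPI`, `SDPI`, `VPIant`,
#'   `DPIant`) and `records` (the per-surface tibble).
#' @examples
#' coh <- generate_cohort(n_subjects = 5, seed = 1)
#' coh$subjects
#' @export
generate_cohort <- function(n_subjects = 47,
                            fraction_range = c(0, 60),
                            index_noise_sd = 5,
                            calibration_visible = default_calibration("visible"),
                            calibration_disclosed = default_calibration("disclosed"),
                            seed = 1) {
  if (n_subjects < 3) abort_input("Need at least 3 subjects.")
  withr::with_seed(seed, {
    f <- runif(n_subjects, fraction_range[1], fraction_range[2])
    svpi <- apply_calibration(calibration_visible, f)
    sdpi <- apply_calibration(calibration_disclosed, f)
    vpi_raw <- svpi + rnorm(n_subjects, 0, index_noise_sd)
    dpi_raw <- sdpi + rnorm(n_subjects, 0, index_noise_sd)
    vpi <- pmin(100, pmax(0, vpi_raw))
    dpi <- pmin(100, pmax(0, dpi_raw))
    n_clamped <- sum(vpi != vpi_raw) + sum(dpi != dpi_raw)
    if (n_clamped > 0.25 * 2 * n_subjects) {
      warn(sprintf(
        "%d of %d generated index values were clamped to [0, 100]; the noise/calibration combination pushes many subjects off-scale.",
        n_clamped, 2L * n_subjects))
    }
    ids <- sprintf("S%03d", seq_len(n_subjects))
    grid <- tidyr::expand_grid(tooth = fdi_teeth(), surface = SURFACES)
    n_surf <- nrow(grid)  # 28 teeth x 4 surfaces = 112
    make_records <- function(id, value, disclosed) {
      pos <- sample(n_surf, round(value * n_surf / 100))
      dplyr::mutate(grid, subject_id = id,
                    plaque_present = dplyr::row_number() %in% pos,
                    disclosed = disclosed, .before = 1)
    }
    records <- dplyr::bind_rows(
      purrr::map2(ids, vpi, make_records, disclosed = FALSE),
      purrr::map2(ids, dpi, make_records, disclosed = TRUE)
    )
    records <- dplyr::select(records, "subject_id", "tooth", "surface",
                             "plaque_present", "disclosed")
    ant_v <- compute_index(records, disclosed = FALSE, scope = "anterior")
    ant_d <- compute_index(records, disclosed = TRUE, scope = "anterior")
    subjects <- tibble(
      subject_id = ids, fraction_pct = f,
      VPI = vpi, DPI = dpi, SVPI = svpi, SDPI = sdpi,
      VPIant = ant_v$value_pct[match(ids, ant_v$subject_id)],
      DPIant = ant_d$value_pct[match(ids, ant_d$subject_id)]
    )
    structure(list(subjects = subjects, records = records,
                   spec = list(n_subjects = n_subjects,
                               fraction_range = fraction_range,
                               index_noise_sd = index_noise_sd,
                               seed = seed)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d surface records, index noise sd %.3g\n",
    nrow(x$subjects), nrow(x$records), x$spec$index_noise_sd))
  invisible(x)
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `subjects.csv` (the cohort table) and `surface_records.csv`
#' (per-surface records in the [read_surface_records()] format) to `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort_input("`cohort` must come from `generate_cohort()`.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.csv"),
             records = file.path(dir, "surface_records.csv"))
  readr::write_csv(cohort$subjects, paths["subjects"])
  recs <- dplyr::mutate(cohort$records,
                        plaque_present = as.integer(.data$plaque_present),
                        disclosed = as.integer(.data$disclosed))
  readr::write_csv(recs, paths["records"])
  invisible(paths)
}
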