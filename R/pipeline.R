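# The assembled pipeline: image + mask -> crop -> HSB -> plaque detection ->
# fraction -> calibration -> report; cohort runs add clinical indices and the
# validation correlation table. Reports are self-describing: the
# configuration is echoed into every report, so a run can be reproduced from
# its own output.

#' Pipeline run configuration
#'
#' @param mode Which selfie index to compute: `"visible"` (SVPI, plain smile)
#'   or `"disclosed"` (SDPI, after disclosing solution).
#' @param threshold_mode `"auto_otsu"` or `"fixed_band"` (see
#'   [detect_plaque()]).
#' @param band Saturation window `c(low, high)`; required iff
#'   `threshold_mode = "fixed_band"`.
#' @param calibration A `calibration_model`, a path to a calibration JSON
#'   file, or `NULL` for the published default of `mode`.
#' @param fraction_scale Feed the calibration the `"percent"` fraction
#'   (default, the self-consistent reading) or the `"unit"` ratio PA/TA.
#' @param plaque_class Which Otsu class is plaque (`"high"` or `"low"`).
#' @param output_dir Directory for JSON/CSV/PNG outputs, or `NULL` to skip
#'   writing.
#' @param overlay Also write an overlay PNG with plaque pixels in black?
#' @param log_level `"info"` (progress to stderr) or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("visible", "disclosed"),
                       threshold_mode = c("auto_otsu", "fixed_band"),
                       band = NULL,
                       calibration = NULL,
                       fraction_scale = c("percent", "unit"),
                       plaque_class = c("high", "low"),
                       output_dir = NULL,
                       overlay = FALSE,
                       log_level = c("info", "quiet")) {
  mode <- match.arg(mode)
  threshold_mode <- match.arg(threshold_mode)
  fraction_scale <- match.arg(fraction_scale)
  plaque_class <- match.arg(plaque_class)
  log_level <- match.arg(log_level)
  if (threshold_mode == "fixed_band" && (is.null(band) || length(band) != 2L)) {
    abort_input("`fixed_band` threshold mode requires `band = c(low, high)`.")
  }
  if (threshold_mode == "auto_otsu" && !is.null(band)) {
    abort_input("`band` is only meaningful with `threshold_mode = \"fixed_band\"`.")
  }
  if (is.character(calibration)) calibration <- read_calibration(calibration)
  if (!is.null(calibration) && !inherits(calibration, "calibration_model")) {
    abort_input("`calibration` must be a calibration_model, a JSON path, or NULL.")
  }
  structure(
    list(mode = mode, threshold_mode = threshold_mode, band = band,
         calibration = calibration %||% default_calibration(mode),
         fraction_scale = fraction_scale, plaque_class = plaque_class,
         output_dir = output_dir, overlay = overlay, log_level = log_level),
    class = "run_config"
  )
}

cli_log <- function(config, fmt, ...) {
  if (config$log_level != "quiet") {
    message(sprintf(fmt, ...))
  }
}

config_echo <- function(config) {
  list(mode = config$mode, threshold_mode = config$threshold_mode,
       band = config$band,
       calibration = list(mode = config$calibration$mode,
                          intercept = config$calibration$intercept,
                          slope = config$calibration$slope),
       fraction_scale = config$fraction_scale,
       plaque_class = config$plaque_class)
}

#' Measure one subject's smile image
#'
#' Runs the full single-image pipeline: read the photograph and its tooth
#' mask, crop to the mask, decompose to HSB, select plaque pixels on the
#' saturation channel, form the percent plaque fraction and map it through
#' the calibration model to the selfie index. When `config$output_dir` is
#' set, a JSON report (and optionally an overlay PNG with plaque in black)
#' is written.
#'
#' @param image_path Path to the smile photograph (PNG or JPEG).
#' @param mask_path Path to the tooth-mask PNG (same dimensions).
#' @param config A [run_config()].
#' @param subject_id Identifier used in the report and output file names.
#' @return A `subject_report`: list with `subject_id`, `pa`, `ta`,
#'   `fraction_pct`, `selfie_index` (unclamped), `selfie_index_clamped`,
#'   `index_name` (`"SVPI"` or `"SDPI"`), the detection provenance and the
#'   echoed configuration.
#' @export
run_subject <- function(image_path, mask_path, config = run_config(),
                        subject_id = NULL) {
  if (!inherits(config, "run_config")) {
    abort_input("`config` must come from `run_config()`.")
  }
  subject_id <- subject_id %||%
    tools::file_path_sans_ext(basename(image_path))
  image <- read_smile_image(image_path)
  mask <- read_tooth_mask(mask_path, expected_dim = dim(image)[1:2])
  crop <- crop_to_mask(image, mask)
  hsb <- rgb_to_hsb(crop$image)
  meas <- detect_plaque(hsb, crop$mask,
                        mode = config$threshold_mode, band = config$band,
                        plaque_class = config$plaque_class)
  fraction_used <- if (config$fraction_scale == "percent") {
    meas$fraction_pct
  } else {
    meas$fraction_pct / 100
  }
  index <- apply_calibration(config$calibration, fraction_used)
  report <- structure(
    list(subject_id = subject_id,
         pa = meas$pa, ta = meas$ta, fraction_pct = meas$fraction_pct,
         selfie_index = index,
         selfie_index_clamped = min(100, max(0, index)),
         index_name = if (config$mode == "visible") "SVPI" else "SDPI",
         threshold = meas$threshold, band = meas$band,
         config = config_echo(config)),
    class = "subject_report"
  )
  cli_log(config, "[%s] PA = %d, TA = %d, fraction = %.2f%%, %s = %.2f",
          subject_id, meas$pa, meas$ta, meas$fraction_pct,
          report$index_name, index)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      unclass(report),
      file.path(config$output_dir, paste0(subject_id, "_report.json")),
      auto_unbox = TRUE, digits = NA, null = "null")
    if (isTRUE(config$overlay)) {
      write_smile_image(
        plaque_overlay(crop$image, meas),
        file.path(config$output_dir, paste0(subject_id, "_overlay.png")))
    }
  }
  report
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report> %s: fraction %.2f%% -> %s %.2f (clamped %.2f)\n",
              x$subject_id, x$fraction_pct, x$index_name, x$selfie_index,
              x$selfie_index_clamped))
  invisible(x)
}

#' @describeIn run_subject One-row tibble of the report.
#' @param x A `subject_report`.
#' @param ... Unused.
#' @method tidy subject_report
#' @export
tidy.subject_report <- function(x, ...) {
  tibble(subject_id = x$subject_id, pa = x$pa, ta = x$ta,
         fraction_pct = x$fraction_pct, index_name = x$index_name,
         selfie_index = x$selfie_index,
         selfie_index_clamped = x$selfie_index_clamped)
}

#' Run the pipeline over a cohort manifest
#'
#' Applies [run_subject()] to every row of a manifest (columns `subject_id`,
#' `image`, `mask`). Subjects whose image or mask fails are logged and
#' skipped; the run fails only if every subject fails. When per-surface
#' clinical records are supplied, the visible and disclosed indices
#' (full-mouth and anterior) are computed per subject and the
#' selfie-vs-clinical Spearman correlation table is produced.
#'
#' @param manifest Data frame or CSV path with columns `subject_id`, `image`,
#'   `mask`.
#' @param records Optional per-surface records (data frame or CSV in the
#'   [read_surface_records()] format).
#' @param config A [run_config()].
#' @return A `cohort_report`: `subjects` (per-subject tibble), `correlations`
#'   (a `correlation_matrix`, or `NULL` with < 3 subjects), `skipped`
#'   (tibble of failures), `n_failed`.
#' @export
run_cohort <- function(manifest, records = NULL, config = run_config()) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      abort_input(sprintf("Manifest file not found: '%s'", manifest))
    }
    manifest <- readr::read_csv(manifest, col_types = readr::cols(
      subject_id = readr::col_character(),
      image = readr::col_character(),
      mask = readr::col_character()))
  }
  if (!all(c("subject_id", "image", "mask") %in% names(manifest))) {
    abort_input("Manifest needs columns `subject_id`, `image`, `mask`.")
  }
  if (is.character(records)) records <- read_surface_records(records)

  results <- purrr::pmap(manifest[c("subject_id", "image", "mask")],
    function(subject_id, image, mask) {
      tryCatch(
        list(ok = run_subject(image, mask, config, subject_id = subject_id)),
        error = function(e) list(err = conditionMessage(e),
                                 subject_id = subject_id))
    })
  ok <- purrr::keep(results, ~ !is.null(.x$ok))
  failed <- purrr::keep(results, ~ is.null(.x$ok))
  skipped <- tibble(
    subject_id = purrr::map_chr(failed, "subject_id"),
    error = purrr::map_chr(failed, "err"))
  for (i in seq_len(nrow(skipped))) {
    cli_log(config, "skipped %s: %s", skipped$subject_id[i], skipped$error[i])
  }
  if (length(ok) == 0L) {
    abort_input("All subjects failed; no cohort report produced.")
  }
  subjects <- purrr::map_dfr(ok, ~ tidy(.x$ok))
  index_col <- unique(subjects$index_name)
  subjects <- dplyr::rename(subjects, !!index_col := "selfie_index")
  subjects$index_name <- NULL

  if (!is.null(records)) {
    validate_surface_records(records)
    add_index <- function(tbl, disclosed, scope, name) {
      idx <- tryCatch(compute_index(records, disclosed, scope),
                      selfieplaque_input_error = function(e) NULL)
      if (is.null(idx)) return(tbl)
      dplyr::left_join(
        tbl, dplyr::select(idx, "subject_id", !!name := "value_pct"),
        by = "subject_id")
    }
    subjects <- subjects |>
      add_index(FALSE, "full_mouth", "VPI") |>
      add_index(TRUE, "full_mouth", "DPI") |>
      add_index(FALSE, "anterior", "VPIant") |>
      add_index(TRUE, "anterior", "DPIant")
  }

  numeric_cols <- subjects[setdiff(names(subjects),
                                   c("subject_id", "pa", "ta",
                                     "selfie_index_clamped"))]
  correlations <- if (nrow(subjects) >= 3 && ncol(numeric_cols) >= 2) {
    correlation_matrix(numeric_cols)
  } else {
    NULL
  }
  report <- structure(
    list(subjects = subjects, correlations = correlations,
         skipped = skipped, n_failed = nrow(skipped),
         config = config_echo(config)),
    class = "cohort_report"
  )
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(subjects, file.path(config$output_dir, "cohort.csv"))
    jsonlite::write_json(
      list(subjects = subjects, skipped = skipped,
           config = report$config),
      file.path(config$output_dir, "cohort.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(correlations)) {
      write_correlation(correlations,
                        file.path(config$output_dir, "correlations"))
    }
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects (%d skipped)\n",
              nrow(x$subjects), x$n_failed))
  if (!is.null(x$correlations)) print(x$correlations)
  invisible(x)
}
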