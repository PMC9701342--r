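# Clinical reference indices from per-surface dichotomous records.
#
# Both reference indices score each tooth surface present/absent for plaque
# and report the percent of positive surfaces: the visible plaque index
# (VPI, Ainamo & Bay — no staining) and the disclosed plaque index (DPI,
# O'Leary — after disclosing dye). Four surfaces per tooth (buccal, lingual,
# mesial, distal), third molars excluded; missing teeth simply contribute no
# records, so the denominator is the observed surface count.

SURFACES <- c("buccal", "lingual", "mesial", "distal")

# FDI two-digit codes, third molars (x8) excluded
fdi_teeth <- function() {
  as.vector(outer(10L * 1:4, 1:7, `+`))
}

#' Anterior teeth (FDI codes)
#'
#' The twelve incisors and canines: 13–23 and 33–43 in FDI notation.
#'
#' @return Integer vector of 12 FDI codes.
#' @export
anterior_teeth <- function() {
  as.vector(outer(10L * 1:4, 1:3, `+`))
}

validate_surface_records <- function(records) {
  needed <- c("tooth", "surface", "plaque_present", "disclosed")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    abort_input(sprintf("Surface records need columns: %s.",
                        paste(needed, collapse = ", ")))
  }
  bad_tooth <- setdiff(unique(records$tooth), fdi_teeth())
  if (length(bad_tooth) > 0) {
    abort_input(sprintf(
      "Invalid FDI tooth code(s) (third molars are excluded): %s",
      paste(bad_tooth, collapse = ", ")))
  }
  bad_surface <- setdiff(unique(records$surface), SURFACES)
  if (length(bad_surface) > 0) {
    abort_input(sprintf("Invalid surface tag(s): %s (expected %s)",
                        paste(bad_surface, collapse = ", "),
                        paste(SURFACES, collapse = "/")))
  }
  if (!is.logical(records$plaque_present) || !is.logical(records$disclosed) ||
      anyNA(records$plaque_present) || anyNA(records$disclosed)) {
    abort_input("`plaque_present` and `disclosed` must be logical without NA.")
  }
  key_cols <- intersect(c("subject_id", "tooth", "surface", "disclosed"),
                        names(records))
  if (anyDuplicated(records[key_cols])) {
    abort_input("Duplicate (tooth, surface) records within a disclosed flag.")
  }
  invisible(records)
}

#' Read per-surface plaque records from CSV
#'
#' Strict comma-separated format with header
#' `subject_id,tooth,surface,plaque_present,disclosed`: `tooth` is a two-digit
#' FDI code, `surface` one of buccal/lingual/mesial/distal, and the last two
#' columns are 0/1 flags (plaque seen on that surface; scored after
#' disclosing solution).
#'
#' @param path CSV file path.
#' @return A validated tibble with `plaque_present`/`disclosed` as logicals.
#' @export
read_surface_records <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("Surface-record file not found: '%s'", path))
  }
  recs <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      tooth = readr::col_integer(),
      surface = readr::col_character(),
      plaque_present = readr::col_integer(),
      disclosed = readr::col_integer()
    )
  )
  expected <- c("subject_id", "tooth", "surface", "plaque_present", "disclosed")
  if (!identical(names(recs), expected)) {
    abort_input(sprintf("Surface-record CSV header must be exactly: %s",
                        paste(expected, collapse = ",")))
  }
  recs$plaque_present <- recs$plaque_present > 0
  recs$disclosed <- recs$disclosed > 0
  validate_surface_records(recs)
  recs
}

#' Restrict surface records to the anterior teeth
#'
#' Keeps only records whose FDI code is one of the twelve incisors and
#' canines ([anterior_teeth()]); row order is preserved.
#'
#' @param records Surface-record data frame.
#' @return The anterior subset, same columns.
#' @export
anterior_subset <- function(records) {
  validate_surface_records(records)
  records[records$tooth %in% anterior_teeth(), , drop = FALSE]
}

#' Compute a clinical plaque index
#'
#' Percent of examined tooth surfaces scored positive for plaque, the common
#' definition of the visible plaque index (records with `disclosed = FALSE`)
#' and the O'Leary disclosed index (`disclosed = TRUE`). With
#' `scope = "anterior"` only the twelve anterior teeth enter, giving the
#' partial indices VPIant / DPIant. When a `subject_id` column is present the
#' index is computed per subject.
#'
#' @param records Surface-record data frame (see [read_surface_records()]).
#' @param disclosed Score the disclosed (`TRUE`) or visible (`FALSE`) records.
#' @param scope `"full_mouth"` or `"anterior"`.
#' @return A tibble with one row per subject (or a single row when there is
#'   no `subject_id` column): `scope`, `disclosed`, `n_surfaces`,
#'   `n_positive`, `value_pct`.
#' @examples
#' recs <- tibble::tibble(tooth = c(11, 11, 16, 16),
#'                        surface = c("buccal", "lingual", "buccal", "lingual"),
#'                        plaque_present = c(TRUE, FALSE, TRUE, TRUE),
#'                        disclosed = FALSE)
#' compute_index(recs, disclosed = FALSE)
#' @export
compute_index <- function(records, disclosed,
                          scope = c("full_mouth", "anterior")) {
  scope <- match.arg(scope)
  validate_surface_records(records)
  if (!is.logical(disclosed) || length(disclosed) != 1L || is.na(disclosed)) {
    abort_input("`disclosed` must be TRUE or FALSE.")
  }
  sub <- records[records$disclosed == disclosed, , drop = FALSE]
  if (scope == "anterior") sub <- sub[sub$tooth %in% anterior_teeth(), , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort_input(sprintf("No %s records in scope '%s'.",
                        if (disclosed) "disclosed" else "visible", scope))
  }
  grouping <- if ("subject_id" %in% names(sub)) "subject_id" else character()
  out <- sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_surfaces = dplyr::n(),
      n_positive = sum(.data$plaque_present),
      value_pct = 100 * sum(.data$plaque_present) / dplyr::n(),
      .groups = "drop"
    )
  dplyr::mutate(out, scope = scope, disclosed = disclosed,
                .before = "n_surfaces")
}

#' Mean paired difference between two index series
#'
#' Arithmetic mean of `b - a` over paired subjects, the summary used to
#' compare disclosed with visible scores across a cohort.
#'
#' @param a,b Equal-length numeric vectors of paired index values (percent).
#' @return Mean difference `mean(b - a)` in percent.
#' @examples
#' mean_index_difference(c(10, 20), c(50, 52))
#' @export
mean_index_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b)) {
    abort_input("`a` and `b` must be equal-length numeric vectors.")
  }
  if (length(a) == 0L) abort_input("Need at least one pair.")
  mean(b - a)
}
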