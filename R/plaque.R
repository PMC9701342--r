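# Plaque detection inside the tooth mask and the PA/TA fraction.
#
# Only the saturation channel is constrained: hue and brightness are left at
# the full [0, 255] band. Disclosing dye (and, less strongly, visible plaque)
# raises saturation relative to clean enamel, so the high-saturation Otsu
# class is taken as plaque by default; `plaque_class = "low"` flips this.

#' Detect plaque pixels by saturation thresholding
#'
#' Selects plaque pixels inside the tooth mask from the saturation plane of an
#' HSB image. Two modes reproduce the two readings of the manual protocol:
#'
#' * `"auto_otsu"` computes the Otsu threshold on the saturation histogram
#'   restricted to the mask and takes one class (by default the
#'   high-saturation class, `saturation > t`) as plaque — the automatic
#'   surrogate for the operator's adjustment.
#' * `"fixed_band"` takes a user-supplied closed saturation window
#'   `band = c(low, high)` — the operator's manual selection made explicit.
#'
#' @param hsb An `hsb_image` from [rgb_to_hsb()].
#' @param mask Logical tooth mask of matching dimensions with at least one
#'   `TRUE` pixel.
#' @param mode `"auto_otsu"` or `"fixed_band"`.
#' @param band Length-2 numeric `c(low, high)`, required for `"fixed_band"`.
#' @param plaque_class For `"auto_otsu"`: which Otsu class is plaque,
#'   `"high"` (default) or `"low"`.
#' @return A `plaque_measurement`: list with `plaque` (logical raster, always
#'   a subset of `mask`), `pa` (plaque pixel count), `ta` (tooth pixel count),
#'   `fraction_pct` (`100 * pa / ta`), `mode`, and `threshold` (Otsu level) or
#'   `band` as applicable.
#' @seealso [plaque_fraction()], [apply_calibration()]
#' @export
detect_plaque <- function(hsb, mask,
                          mode = c("auto_otsu", "fixed_band"),
                          band = NULL,
                          plaque_class = c("high", "low")) {
  hsb <- as_hsb_image(hsb)
  mode <- match.arg(mode)
  plaque_class <- match.arg(plaque_class)
  sat <- hsb$saturation
  check_mask_dims(mask, dim(sat))
  ta <- total_area(mask)
  if (ta == 0L) {
    abort_input("Empty tooth mask: total tooth area is zero.")
  }
  if (mode == "auto_otsu") {
    t <- otsu_threshold(channel_histogram(sat, mask = mask))
    plaque <- if (plaque_class == "high") (sat > t) & mask else (sat <= t) & mask
    threshold <- t
    band_used <- NULL
  } else {
    if (is.null(band) || length(band) != 2L) {
      abort_input("`fixed_band` mode requires `band = c(low, high)`.")
    }
    plaque <- apply_band_threshold(sat, band[1], band[2], mask = mask)
    threshold <- NULL
    band_used <- as.numeric(band)
  }
  pa <- sum(plaque)
  structure(
    list(plaque = plaque, pa = pa, ta = ta,
         fraction_pct = plaque_fraction(pa, ta),
         mode = mode, plaque_class = if (mode == "auto_otsu") plaque_class else NULL,
         threshold = threshold, band = band_used),
    class = "plaque_measurement"
  )
}

#' Plaque-area fraction in percent
#'
#' The core measurement of the pipeline: the percentage of the tooth area
#' covered by plaque, `100 * PA / TA`.
#'
#' @param pa Plaque pixel count, `0 <= pa <= ta`.
#' @param ta Tooth pixel count, `> 0`.
#' @return Percent fraction in `[0, 100]`.
#' @examples
#' plaque_fraction(125, 1000)
#' @export
plaque_fraction <- function(pa, ta) {
  if (!is.numeric(pa) || !is.numeric(ta) || length(pa) != 1L || length(ta) != 1L) {
    abort_input("`pa` and `ta` must be single counts.")
  }
  if (ta <= 0) abort_input("Total tooth area must be positive.")
  if (pa < 0 || pa > ta) abort_input("Plaque area must satisfy 0 <= PA <= TA.")
  100 * pa / ta
}

#' @export
print.plaque_measurement <- function(x, ...) {
  cat(sprintf("<plaque_measurement> PA = %d, TA = %d, fraction = %.2f%% (%s%s)\n",
              x$pa, x$ta, x$fraction_pct, x$mode,
              if (!is.null(x$threshold)) sprintf(", Otsu t = %d", x$threshold)
              else sprintf(", band [%g, %g]", x$band[1], x$band[2])))
  invisible(x)
}

#' @describeIn detect_plaque One-row tibble of the measurement (PA, TA,
#'   fraction, mode and threshold/band provenance).
#' @param x A `plaque_measurement`.
#' @param ... Unused.
#' @method tidy plaque_measurement
#' @export
tidy.plaque_measurement <- function(x, ...) {
  tibble(
    pa = x$pa, ta = x$ta, fraction_pct = x$fraction_pct, mode = x$mode,
    plaque_class = x$plaque_class %||% NA_character_,
    threshold = x$threshold %||% NA_integer_,
    band_low = if (is.null(x$band)) NA_real_ else x$band[1],
    band_high = if (is.null(x$band)) NA_real_ else x$band[2]
  )
}

#' Overlay detected plaque on an image
#'
#' Renders the source image with detected plaque pixels painted black, the
#' standard presentation of the procedure's output.
#'
#' @param image The `smile_image` the measurement was made on (same
#'   dimensions as the plaque raster).
#' @param measurement A `plaque_measurement`.
#' @return A `smile_image` with plaque pixels set to (0, 0, 0).
#' @export
plaque_overlay <- function(image, measurement) {
  image <- as_smile_image(image)
  if (!inherits(measurement, "plaque_measurement")) {
    abort_input("`measurement` must be a `plaque_measurement`.")
  }
  check_mask_dims(measurement$plaque, dim(image)[1:2])
  out <- unclass(image)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[measurement$plaque] <- 0
    out[, , ch] <- plane
  }
  smile_image(out)
}

#' Plot a plaque measurement as an overlay image
#'
#' @param object A `plaque_measurement`.
#' @param image The source `smile_image`.
#' @param ... Unused.
#' @return A ggplot object showing the image with plaque in black.
#' @method autoplot plaque_measurement
#' @export
autoplot.plaque_measurement <- function(object, image, ...) {
  over <- plaque_overlay(image, object)
  d <- dim(over)
  df <- tidyr::expand_grid(row = seq_len(d[1]), col = seq_len(d[2]))
  df$fill <- grDevices::rgb(unclass(over)[, , 1] / 255,
                            unclass(over)[, , 2] / 255,
                            unclass(over)[, , 3] / 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(
      title = sprintf("Plaque %.1f%% of tooth area (PA = %d, TA = %d)",
                      object$fraction_pct, object$pa, object$ta))
}
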