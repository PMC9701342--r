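# Linear calibration from anterior plaque-area fraction to full-mouth index.
#
# The selfie indices are linear maps of the percent plaque fraction measured
# on the six anterior teeth:
#
#   SVPI = -7.5  + 1.14 * fraction_pct   (visible plaque)
#   SDPI = 40.62 + 0.44 * fraction_pct   (after disclosing dye)
#
# The published coefficients ship as defaults; new cohorts refit by ordinary
# least squares. Fraction is the PERCENT ratio 100*PA/TA: with a unit ratio
# in [0, 1] the visible-mode intercept of -7.5 could never be overcome across
# the observed range, so percent is the only self-consistent reading (a
# `fraction_scale` switch in the run configuration still exposes the unit
# reading for comparison).

#' Construct a calibration model
#'
#' A linear map `index = intercept + slope * fraction_pct` from the anterior
#' plaque-area fraction (percent) to a full-mouth plaque index (percent).
#'
#' @param intercept Intercept, index percent units.
#' @param slope Slope, index percent per percent plaque fraction.
#' @param mode `"visible"` (SVPI) or `"disclosed"` (SDPI).
#' @param fit Optional underlying `lm` fit (kept by [fit_calibration()]).
#' @return A `calibration_model`.
#' @export
calibration_model <- function(intercept, slope,
                              mode = c("visible", "disclosed"),
                              fit = NULL) {
  mode <- match.arg(mode)
  if (!is.finite(intercept) || !is.finite(slope)) {
    abort_input("Calibration coefficients must be finite.")
  }
  structure(
    list(intercept = as.numeric(intercept), slope = as.numeric(slope),
         mode = mode, fit = fit),
    class = "calibration_model"
  )
}

#' Default (published) calibration models
#'
#' The shipped coefficients of the selfie visible-plaque index
#' (`SVPI = -7.5 + 1.14 * fraction`) and the selfie disclosed-plaque index
#' (`SDPI = 40.62 + 0.44 * fraction`), with fraction in percent.
#'
#' @param mode `"visible"` or `"disclosed"`.
#' @return A `calibration_model`.
#' @examples
#' apply_calibration(default_calibration("visible"), 0)
#' @export
default_calibration <- function(mode = c("visible", "disclosed")) {
  mode <- match.arg(mode)
  switch(mode,
    visible = calibration_model(-7.5, 1.14, mode = "visible"),
    disclosed = calibration_model(40.62, 0.44, mode = "disclosed")
  )
}

#' Map a plaque-area fraction to a full-mouth index estimate
#'
#' Evaluates `intercept + slope * fraction_pct`. The raw value is NOT clamped
#' to `[0, 100]` — the visible-mode intercept is negative, so small fractions
#' legitimately map below zero; set `clamp = TRUE` for a reporting-friendly
#' value truncated to the index scale.
#'
#' @param model A `calibration_model`.
#' @param fraction_pct Plaque-area fraction(s) in percent.
#' @param clamp Clamp the result to `[0, 100]`?
#' @return Numeric index estimate(s), percent scale.
#' @examples
#' apply_calibration(default_calibration("disclosed"), 50)
#' @export
apply_calibration <- function(model, fraction_pct, clamp = FALSE) {
  if (!inherits(model, "calibration_model")) {
    abort_input("`model` must be a `calibration_model`.")
  }
  if (!is.numeric(fraction_pct) || anyNA(fraction_pct) ||
      any(!is.finite(fraction_pct))) {
    abort_input("`fraction_pct` must be finite numeric.")
  }
  out <- model$intercept + model$slope * fraction_pct
  if (clamp) out <- pmin(100, pmax(0, out))
  out
}

#' Fit a calibration model by ordinary least squares
#'
#' Regresses the full-mouth index on the anterior plaque-area fraction over a
#' table of calibration pairs, the procedure used to derive the published
#' equations from a calibration cohort.
#'
#' @param pairs Data frame with numeric columns `fraction_pct` and
#'   `full_mouth_index` (at least 3 rows; the fractions must not all be
#'   identical).
#' @param mode `"visible"` or `"disclosed"`.
#' @return A `calibration_model` carrying the underlying [stats::lm] fit, so
#'   [tidy()] and [glance()] report coefficient and fit statistics.
#' @examples
#' pairs <- tibble::tibble(fraction_pct = c(0, 50, 100),
#'                         full_mouth_index = c(0, 50, 100))
#' coef(fit_calibration(pairs, "visible"))
#' @export
fit_calibration <- function(pairs, mode = c("visible", "disclosed")) {
  mode <- match.arg(mode)
  if (!is.data.frame(pairs) ||
      !all(c("fraction_pct", "full_mouth_index") %in% names(pairs))) {
    abort_input("`pairs` needs columns `fraction_pct` and `full_mouth_index`.")
  }
  x <- pairs$fraction_pct
  y <- pairs$full_mouth_index
  if (length(x) < 3L) {
    abort_input("Calibration requires at least 3 pairs.")
  }
  if (anyNA(x) || anyNA(y)) abort_input("Calibration pairs must not contain NA.")
  if (sd(x) == 0) {
    abort_input("Plaque fractions are all identical: slope is unidentifiable.")
  }
  fit <- lm(full_mouth_index ~ fraction_pct, data = pairs)
  calibration_model(coef(fit)[[1]], coef(fit)[[2]], mode = mode, fit = fit)
}

#' @export
print.calibration_model <- function(x, ...) {
  label <- if (x$mode == "visible") "SVPI" else "SDPI"
  cat(sprintf("<calibration_model> %s = %.4g + %.4g * fraction_pct (%s%s)\n",
              label, x$intercept, x$slope, x$mode,
              if (is.null(x$fit)) ", published defaults" else ", fitted"))
  invisible(x)
}

#' @export
coef.calibration_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.calibration_model <- function(object, fraction_pct, clamp = FALSE, ...) {
  apply_calibration(object, fraction_pct, clamp = clamp)
}

#' Tidy a calibration model
#'
#' One row per coefficient; when the model carries an OLS fit the standard
#' errors, t statistics and p-values of the fit are included.
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` and, for fitted models,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy calibration_model
#' @export
tidy.calibration_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(term = c("(Intercept)", "fraction_pct"),
                  estimate = c(x$intercept, x$slope)))
  }
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' Glance at a calibration model
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return One-row tibble: `mode`, `intercept`, `slope` and, for fitted
#'   models, `r.squared`, `sigma`, `nobs`.
#' @method glance calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  base <- tibble(mode = x$mode, intercept = x$intercept, slope = x$slope)
  if (is.null(x$fit)) return(base)
  s <- summary(x$fit)
  dplyr::mutate(base, r.squared = s$r.squared, sigma = s$sigma,
                nobs = stats::nobs(x$fit))
}

#' Plot a calibration model over its range
#'
#' @param object A `calibration_model`.
#' @param ... Unused.
#' @return A ggplot of the calibration line (with the fitted pairs when the
#'   model carries a fit).
#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, ...) {
  label <- if (object$mode == "visible") "SVPI" else "SDPI"
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope) +
    ggplot2::xlim(0, 100) +
    ggplot2::labs(x = "plaque-area fraction (% of tooth area)",
                  y = sprintf("%s (index %%)", label),
                  title = sprintf("%s = %.3g + %.3g × fraction",
                                  label, object$intercept, object$slope))
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_point(
      data = object$fit$model,
      ggplot2::aes(x = .data$fraction_pct, y = .data$full_mouth_index))
  }
  p
}

#' Read or write a calibration model as JSON
#'
#' The on-disk form is `{"mode": "visible", "intercept": -7.5, "slope": 1.14}`.
#'
#' @param path JSON file path.
#' @return `read_calibration()` returns a `calibration_model`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("Calibration file not found: '%s'", path))
  }
  obj <- try(jsonlite::read_json(path, simplifyVector = TRUE), silent = TRUE)
  if (inherits(obj, "try-error") ||
      !all(c("mode", "intercept", "slope") %in% names(obj))) {
    abort_input(sprintf(
      "Calibration JSON must hold fields mode, intercept, slope: '%s'", path))
  }
  calibration_model(obj$intercept, obj$slope, mode = obj$mode)
}

#' @rdname read_calibration
#' @param model A `calibration_model`.
#' @export
write_calibration <- function(model, path) {
  if (!inherits(model, "calibration_model")) {
    abort_input("`model` must be a `calibration_model`.")
  }
  jsonlite::write_json(
    list(mode = model$mode, intercept = model$intercept, slope = model$slope),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
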