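# Tooth-region masks.
#
# Manual segmentation of the six anterior teeth (done with an object-selection
# tool on the photographs) enters the pipeline as a binary mask file: nonzero
# pixels mean "tooth". The mask defines the total tooth area TA, the
# denominator of the plaque fraction.

#' Read a tooth-region mask from a PNG file
#'
#' Accepts a single-channel or RGB PNG; any pixel with a nonzero value in any
#' colour channel is tooth (so antialiased edge pixels count as tooth). An
#' alpha channel is ignored.
#'
#' @param path Path to the mask PNG.
#' @param expected_dim Optional `c(rows, cols)` to validate against the image
#'   the mask belongs to.
#' @return Logical `H x W` matrix with at least one `TRUE` pixel.
#' @export
read_tooth_mask <- function(path, expected_dim = NULL) {
  if (!file.exists(path)) {
    abort_input(sprintf("Mask file not found: '%s'", path))
  }
  raw <- try(png::readPNG(path), silent = TRUE)
  if (inherits(raw, "try-error")) {
    abort_input(sprintf("Could not decode mask PNG: '%s'", path))
  }
  if (length(dim(raw)) == 3L) {
    nch <- min(dim(raw)[3], 3L)  # drop alpha
    raw <- apply(raw[, , seq_len(nch), drop = FALSE], c(1, 2), max)
  }
  mask <- raw > 0
  if (!is.null(expected_dim) && !identical(dim(mask), as.integer(expected_dim))) {
    abort_input(sprintf(
      "Mask dimensions (%d x %d) do not match expected (%d x %d): '%s'",
      dim(mask)[1], dim(mask)[2], expected_dim[1], expected_dim[2], path))
  }
  if (!any(mask)) {
    abort_input(sprintf("Empty tooth mask (no nonzero pixels): '%s'", path))
  }
  mask
}

#' Write a tooth mask to a grayscale PNG
#'
#' @param mask Logical `H x W` matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_tooth_mask <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_input("`mask` must be a logical matrix.")
  }
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' Total tooth area in pixels
#'
#' The count of `TRUE` pixels in a tooth mask: the TA denominator of the
#' plaque-area fraction.
#'
#' @param mask Logical matrix.
#' @return Non-negative integer pixel count.
#' @export
total_area <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_input("`mask` must be a logical matrix.")
  }
  sum(mask)
}

#' Crop an image to the bounding box of its tooth mask
#'
#' Restricts the image to the smallest rectangle containing the mask and sets
#' every non-tooth pixel to the black sentinel (0, 0, 0). The cropped mask is
#' returned alongside so the sentinel pixels stay excluded from every
#' downstream histogram; the sentinel can therefore never bias a threshold.
#'
#' @param image A [smile_image()] or `H x W x 3` byte array.
#' @param mask Logical matrix of the same `H x W` dimensions with at least one
#'   `TRUE` pixel.
#' @return A list of class `smile_crop`: `image` (the cropped, blanked
#'   `smile_image`), `mask` (the cropped logical mask) and `offset`
#'   (`c(row, col)` of the crop origin in the source image, 1-based).
#' @export
crop_to_mask <- function(image, mask) {
  image <- as_smile_image(image)
  check_mask_dims(mask, dim(image)[1:2])
  if (!any(mask)) {
    abort_input("Empty tooth mask: cannot crop to a mask with no TRUE pixels.")
  }
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub_mask <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  sub_img <- unclass(image)[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  blank <- !sub_mask
  for (ch in 1:3) {
    plane <- sub_img[, , ch]
    plane[blank] <- 0
    sub_img[, , ch] <- plane
  }
  structure(
    list(image = smile_image(sub_img), mask = sub_mask,
         offset = c(row = rows[1], col = cols[1])),
    class = "smile_crop"
  )
}

#' @export
print.smile_crop <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<smile_crop> %d x %d bounding box, TA = %d px\n",
              d[2], d[1], total_area(x$mask)))
  invisible(x)
}
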