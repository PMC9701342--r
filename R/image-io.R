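# Raster I/O and the smile-image container.
#
# A smile image is an H x W x 3 numeric array of byte values in [0, 255]
# (red, green, blue planes), the 24-bit depth the capture protocol produces.

#' Construct a smile image from an RGB byte array
#'
#' Validates and classes an `H x W x 3` array of red/green/blue byte values.
#' All pixel-level functions in the package accept either a classed
#' `smile_image` or a plain array of the same shape.
#'
#' @param pixels Numeric array of dimension `H x W x 3` with values in
#'   `[0, 255]`.
#' @return A `smile_image` object (the validated array with a class attribute).
#' @examples
#' img <- smile_image(array(128, dim = c(4, 6, 3)))
#' dim(img)
#' @export
smile_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort_input("`pixels` must be an H x W x 3 array of RGB byte values.")
  }
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L) {
    abort_input("Image must have at least one row and one column of pixels.")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort_input("All channel values must lie in [0, 255].")
  }
  structure(pixels, class = c("smile_image", "array"))
}

as_smile_image <- function(x) {
  if (inherits(x, "smile_image")) x else smile_image(x)
}

#' @export
print.smile_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<smile_image> %d x %d pixels, RGB in [0, 255]\n", d[2], d[1]))
  invisible(x)
}

#' Read a smile photograph from disk
#'
#' Reads an 8-bit-per-channel PNG or JPEG file into a [smile_image()].
#' Grayscale images are expanded to three identical channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A `smile_image`.
#' @export
read_smile_image <- function(path) {
  if (!file.exists(path)) {
    abort_input(sprintf("Image file not found: '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = try(png::readPNG(path), silent = TRUE),
    jpg = ,
    jpeg = try(jpeg::readJPEG(path), silent = TRUE),
    abort_input(sprintf("Unsupported image format '%s' (use PNG or JPEG): '%s'",
                        ext, path))
  )
  if (inherits(raw, "try-error")) {
    abort_input(sprintf("Could not decode image file: '%s'", path))
  }
  if (length(dim(raw)) == 2L) {
    raw <- array(raw, dim = c(dim(raw), 3L))
  } else if (dim(raw)[3] >= 3L) {
    raw <- raw[, , 1:3, drop = FALSE]
  } else {
    raw <- array(raw[, , 1L], dim = c(dim(raw)[1:2], 3L))
  }
  smile_image(round(raw * 255))
}

#' Write a smile image to a PNG file
#'
#' @param image A `smile_image` or `H x W x 3` byte array.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_smile_image <- function(image, path) {
  image <- as_smile_image(image)
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}
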