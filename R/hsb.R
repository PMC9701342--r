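# Hue-saturation-brightness decomposition, byte-scaled.
#
# All three channels are rescaled to [0, 255] (the 8-bit convention of the
# imaging software the protocol standardises on): hue as degrees * 255/360,
# saturation and brightness as fraction * 255, each rounded to the nearest
# integer. Saturation is the channel the plaque selection manipulates; hue
# and brightness are left unconstrained downstream.

#' Convert an RGB smile image to hue/saturation/brightness planes
#'
#' Standard HSV decomposition (via [grDevices::rgb2hsv()]) with every channel
#' rescaled to the byte range `[0, 255]`: hue is mapped from `[0, 360)`
#' degrees, saturation and brightness from the unit interval, all rounded.
#' Gray pixels (r = g = b) have saturation 0.
#'
#' @param image A [smile_image()] or plain `H x W x 3` byte array.
#' @return An `hsb_image`: a list of three `H x W` integer matrices
#'   (`hue`, `saturation`, `brightness`), each in `[0, 255]`.
#' @examples
#' img <- smile_image(array(c(255, 0, 0), dim = c(1, 1, 3)))
#' rgb_to_hsb(img)$saturation
#' @export
rgb_to_hsb <- function(image) {
  image <- as_smile_image(image)
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1L]),
               as.vector(image[, , 2L]),
               as.vector(image[, , 3L]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  shape <- function(v) matrix(as.integer(round(v * 255)), nrow = d[1], ncol = d[2])
  structure(
    list(hue = shape(hsv["h", ]),
         saturation = shape(hsv["s", ]),
         brightness = shape(hsv["v", ])),
    class = "hsb_image"
  )
}

#' @export
print.hsb_image <- function(x, ...) {
  d <- dim(x$hue)
  cat(sprintf("<hsb_image> %d x %d pixels, H/S/B byte planes\n", d[2], d[1]))
  invisible(x)
}

as_hsb_image <- function(x) {
  if (!inherits(x, "hsb_image")) {
    abort_input("Expected an `hsb_image` (see `rgb_to_hsb()`).")
  }
  x
}
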