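# Histogramming and automatic thresholding of byte channels.

check_byte_raster <- function(channel, arg = "channel") {
  if (!is.matrix(channel) || length(channel) == 0L) {
    abort_input(sprintf("`%s` must be a non-empty numeric matrix.", arg))
  }
  if (anyNA(channel) || min(channel) < 0 || max(channel) > 255) {
    abort_input(sprintf("`%s` values must lie in [0, 255].", arg))
  }
  invisible(channel)
}

check_mask_dims <- function(mask, dims) {
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort_input("`mask` must be a logical matrix.")
  }
  if (!identical(dim(mask), dims)) {
    abort_input(sprintf(
      "Mask dimensions (%d x %d) do not match raster dimensions (%d x %d).",
      dim(mask)[1], dim(mask)[2], dims[1], dims[2]))
  }
  invisible(mask)
}

#' Intensity histogram of a byte channel
#'
#' Counts pixel intensities into 256 bins (levels 0..255), optionally
#' restricted to a logical mask of the same dimensions. Masked-out pixels
#' never contribute, so a sentinel background value cannot bias downstream
#' thresholds.
#'
#' @param channel `H x W` numeric matrix of integer byte values in `[0, 255]`.
#' @param mask Optional `H x W` logical matrix; only `TRUE` pixels are counted.
#' @return A `channel_histogram`: an integer vector of length 256 whose `i`-th
#'   element counts pixels at level `i - 1`; the sum equals the number of
#'   pixels considered.
#' @examples
#' channel_histogram(matrix(7, 2, 2))[8]
#' @export
channel_histogram <- function(channel, mask = NULL) {
  check_byte_raster(channel)
  vals <- round(channel)
  if (!is.null(mask)) {
    check_mask_dims(mask, dim(channel))
    vals <- vals[mask]
  }
  counts <- tabulate(as.integer(vals) + 1L, nbins = 256L)
  structure(counts, class = "channel_histogram")
}

#' @export
print.channel_histogram <- function(x, ...) {
  nz <- which(x > 0L) - 1L
  cat(sprintf("<channel_histogram> %d pixels over %d occupied levels\n",
              sum(x), length(nz)))
  invisible(x)
}

#' Otsu's automatic threshold
#'
#' Selects the intensity level `t` that maximises the between-class variance
#' of the split `{<= t, > t}` of a 256-bin histogram — the classic Otsu
#' criterion. Ties are broken by the smallest maximising level, so the result
#' is deterministic. A histogram with all mass at a single level is
#' degenerate; that level itself is returned, so the lower class selects
#' everything.
#'
#' @param x A `channel_histogram`, or an `H x W` byte matrix (in which case a
#'   histogram is computed first, within `mask` if given).
#' @param mask Optional logical mask, used only when `x` is a raster.
#' @return Integer threshold level in `[0, 255]`.
#' @examples
#' h <- channel_histogram(matrix(c(10, 10, 200, 200), 2, 2))
#' otsu_threshold(h)
#' @export
otsu_threshold <- function(x, mask = NULL) {
  if (!inherits(x, "channel_histogram")) {
    x <- channel_histogram(x, mask = mask)
  }
  counts <- as.numeric(x)
  if (length(counts) != 256L || any(counts < 0)) {
    abort_input("Histogram must hold 256 non-negative counts.")
  }
  n <- sum(counts)
  if (n == 0) {
    abort_input("Cannot threshold an empty histogram (no pixels counted).")
  }
  occupied <- which(counts > 0) - 1L
  if (length(occupied) == 1L) {
    return(occupied)
  }
  levels <- 0:255
  w0 <- cumsum(counts)                 # pixels at or below t
  m0 <- cumsum(levels * counts)        # intensity mass at or below t
  w1 <- n - w0
  total <- m0[256]
  # between-class variance for each candidate t = 0..255; splits with an
  # empty class carry no separation
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (m0[valid] * n - w0[valid] * total)^2 /
    (w0[valid] * w1[valid])
  which.max(sigma_b) - 1L              # which.max takes the first maximiser
}

#' Select pixels inside a closed intensity band
#'
#' Returns the binary raster that is `TRUE` exactly where
#' `low <= value <= high` (both ends inclusive, matching the threshold
#' semantics of standard imaging tools) and, if a mask is supplied, where the
#' mask is `TRUE`.
#'
#' @param channel `H x W` byte matrix.
#' @param low,high Band limits, `0 <= low <= high <= 255`.
#' @param mask Optional logical matrix of the same dimensions.
#' @return Logical `H x W` matrix.
#' @examples
#' apply_band_threshold(matrix(c(99, 100, 200), 1, 3), 100, 200)
#' @export
apply_band_threshold <- function(channel, low, high, mask = NULL) {
  check_byte_raster(channel)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || low < 0 || high > 255 || low > high) {
    abort_input("Band limits must satisfy 0 <= low <= high <= 255.")
  }
  out <- channel >= low & channel <= high
  if (!is.null(mask)) {
    check_mask_dims(mask, dim(channel))
    out <- out & mask
  }
  out
}
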