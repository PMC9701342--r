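# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (brute force, textbook formulas) and never
# share code with the implementation paths they check.

# Otsu by exhaustive search: recompute class weights and means from scratch
# for every candidate threshold.
brute_force_otsu <- function(counts) {
  lv <- 0:255
  best <- -Inf
  best_t <- NA_integer_
  for (t in 0:255) {
    lower <- lv <= t
    w0 <- sum(counts[lower])
    w1 <- sum(counts[!lower])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(lv[lower] * counts[lower]) / w0
    m1 <- sum(lv[!lower] * counts[!lower]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best + 1e-9) {
      best <- v
      best_t <- t
    }
  }
  best_t
}

# Textbook HSV -> RGB conversion from byte-scaled channels (hue byte is
# degrees * 255/360, saturation/value bytes are fraction * 255).
hsb_bytes_to_rgb <- function(h_byte, s_byte, v_byte) {
  h <- h_byte / 255 * 360
  s <- s_byte / 255
  v <- v_byte / 255
  c_ <- v * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- v - c_
  sector <- floor(h / 60) %% 6
  rgb1 <- switch(as.character(sector),
    "0" = c(c_, x, 0), "1" = c(x, c_, 0), "2" = c(0, c_, x),
    "3" = c(0, x, c_), "4" = c(x, 0, c_), "5" = c(c_, 0, x))
  round((rgb1 + m) * 255)
}

# One-pixel image helper
pixel_image <- function(r, g, b) {
  smile_image(array(c(r, g, b), dim = c(1, 1, 3)))
}

# A small clean two-tone smile: uniform low-saturation teeth with a
# high-saturation plaque patch and no noise, for exact-recovery checks.
clean_smile <- function(fraction, seed = 1, width = 240, height = 180) {
  generate_smile(target_fraction_pct = fraction, width = width,
                 height = height, noise_sd = 0, seed = seed)
}

# Enumerated full-mouth surface table: 28 teeth x 4 surfaces, with the first
# `n_pos` surfaces positive.
enumerated_records <- function(n_pos, disclosed = FALSE) {
  teeth <- as.vector(outer(10L * 1:4, 1:7, `+`))
  grid <- expand.grid(surface = c("buccal", "lingual", "mesial", "distal"),
                      tooth = teeth, stringsAsFactors = FALSE)
  tibble::tibble(
    tooth = grid$tooth,
    surface = grid$surface,
    plaque_present = seq_len(nrow(grid)) <= n_pos,
    disclosed = disclosed
  )
}
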