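test_that("auto Otsu recovers a clean bimodal plaque patch exactly", {
  sm <- clean_smile(25, seed = 7)
  meas <- detect_plaque(rgb_to_hsb(sm$image), sm$mask, mode = "auto_otsu")
  expect_equal(meas$fraction_pct, sm$true_fraction_pct)
  expect_equal(meas$plaque, sm$plaque)
  expect_equal(abs(meas$fraction_pct - 25), 0, tolerance = 0.5)
})

test_that("fixed bands reproduce the manual saturation-window semantics", {
  sm <- clean_smile(30, seed = 8)
  hsb <- rgb_to_hsb(sm$image)
  everything <- detect_plaque(hsb, sm$mask, mode = "fixed_band",
                              band = c(0, 255))
  expect_equal(everything$pa, everything$ta)
  expect_equal(everything$fraction_pct, 100)

  sat_present <- sort(unique(hsb$saturation[sm$mask]))
  gap <- setdiff(0:255, sat_present)[1]
  none <- detect_plaque(hsb, sm$mask, mode = "fixed_band", band = c(gap, gap))
  expect_equal(none$pa, 0L)
  expect_equal(none$fraction_pct, 0)

  expect_error(detect_plaque(hsb, sm$mask, mode = "fixed_band"),
               "requires `band")
})

test_that("plaque is always a subset of the mask and bands are monotone", {
  sm <- generate_smile(40, width = 240, height = 180, noise_sd = 4, seed = 9)
  hsb <- rgb_to_hsb(sm$image)
  for (mode_args in list(list(mode = "auto_otsu"),
                         list(mode = "fixed_band", band = c(60, 255)))) {
    meas <- do.call(detect_plaque, c(list(hsb, sm$mask), mode_args))
    expect_true(all(!(meas$plaque & !sm$mask))) # pixelwise subset
  }
  prev <- -1L
  for (low in c(200, 150, 100, 50, 0)) {
    pa <- detect_plaque(hsb, sm$mask, mode = "fixed_band",
                        band = c(low, 255))$pa
    expect_gte(pa, prev)
    prev <- pa
  }
})

test_that("auto Otsu recovers fractions 5..95% within one percentage point", {
  for (f in seq(5, 95, 15)) {
    sm <- generate_smile(f, width = 240, height = 180, noise_sd = 3,
                         seed = 100 + f)
    meas <- detect_plaque(rgb_to_hsb(sm$image), sm$mask)
    expect_lt(abs(meas$fraction_pct - sm$true_fraction_pct), 1,
              label = sprintf("fraction error at %d%%", f))
  }
})

test_that("plaque fraction arithmetic is exact and guarded", {
  expect_equal(plaque_fraction(0, 500), 0)
  expect_equal(plaque_fraction(500, 500), 100)
  expect_equal(plaque_fraction(125, 1000), 12.5)
  expect_error(plaque_fraction(1, 0), "positive")
  expect_error(plaque_fraction(10, 5), "PA <= TA")
  empty <- matrix(FALSE, 4, 4)
  sm <- clean_smile(10)
  expect_error(detect_plaque(rgb_to_hsb(sm$image),
                             matrix(FALSE, nrow(sm$mask), ncol(sm$mask))),
               "[Ee]mpty tooth mask")
})

test_that("measurements tidy into one provenance-carrying row", {
  sm <- clean_smile(20, seed = 4)
  meas <- detect_plaque(rgb_to_hsb(sm$image), sm$mask)
  td <- tidy(meas)
  expect_identical(nrow(td), 1L)
  expect_equal(td$fraction_pct, 100 * td$pa / td$ta)
  expect_equal(td$mode, "auto_otsu")
  expect_false(is.na(td$threshold))
})
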