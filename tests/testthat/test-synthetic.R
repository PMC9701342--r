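test_that("smile generation is deterministic and hits the target fraction", {
  a <- generate_smile(25, width = 240, height = 180, seed = 42)
  b <- generate_smile(25, width = 240, height = 180, seed = 42)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$plaque, b$plaque)
  expect_identical(a$true_fraction_pct, b$true_fraction_pct)
  expect_lte(abs(a$true_fraction_pct - 25), 0.5)

  zero <- clean_smile(0)
  expect_false(any(zero$plaque))
  expect_equal(zero$true_fraction_pct, 0)
  full <- clean_smile(100)
  expect_identical(full$plaque, full$mask)
  expect_equal(full$true_fraction_pct, 100)

  expect_false(any(a$plaque & !a$mask))  # plaque subset of mask
  expect_error(generate_smile(25, width = 16, height = 16), "not reachable")
  expect_error(generate_smile(130), "\\[0, 100\\]")
})

test_that("end-to-end closed loop recovers the generated fraction", {
  for (f in c(10, 45, 80)) {
    sm <- generate_smile(f, width = 240, height = 180, noise_sd = 5,
                         seed = 500 + f)
    meas <- detect_plaque(rgb_to_hsb(sm$image), sm$mask, mode = "auto_otsu")
    expect_lt(abs(meas$fraction_pct - sm$true_fraction_pct), 1)
  }
})

test_that("fixture files round-trip through the measurement pipeline", {
  dir <- withr::local_tempdir()
  sm <- generate_smile(35, width = 240, height = 180, seed = 3)
  paths <- write_smile_fixture(sm, dir, stem = "s1")
  expect_equal(unclass(read_smile_image(paths[["image"]])),
               unclass(sm$image), ignore_attr = TRUE)
  expect_equal(read_tooth_mask(paths[["mask"]]), sm$mask, ignore_attr = TRUE)
})

test_that("cohorts are deterministic and internally consistent", {
  a <- generate_cohort(n_subjects = 8, seed = 21)
  b <- generate_cohort(n_subjects = 8, seed = 21)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$records, b$records)
  expect_named(a$subjects, c("subject_id", "fraction_pct", "VPI", "DPI",
                             "SVPI", "SDPI", "VPIant", "DPIant"))
  # per-surface records reproduce the index column within quantisation
  idx <- compute_index(a$records, disclosed = FALSE)
  merged <- dplyr::left_join(a$subjects, idx, by = "subject_id")
  expect_true(all(abs(merged$VPI - merged$value_pct) <= 100 / 112))
  # selfie columns are exactly the calibration lines
  expect_equal(a$subjects$SVPI,
               apply_calibration(default_calibration("visible"),
                                 a$subjects$fraction_pct))
})

test_that("zero index noise with identity calibration gives perfect rank agreement", {
  ident <- calibration_model(0, 1, "visible")
  coh <- generate_cohort(n_subjects = 12, index_noise_sd = 0,
                         calibration_visible = ident, seed = 9)
  expect_equal(spearman_rank(coh$subjects$fraction_pct, coh$subjects$VPI)$rho, 1)
})

test_that("noisy OLS refit recovers the generative coefficients within 2 SE", {
  hits <- 0
  for (s in 1:25) {
    coh <- generate_cohort(n_subjects = 47, seed = 700 + s)
    pairs <- dplyr::transmute(coh$subjects, fraction_pct,
                              full_mouth_index = DPI)
    td <- tidy(fit_calibration(pairs, "disclosed"))
    hits <- hits +
      all(abs(td$estimate - c(40.62, 0.44)) <= 2 * td$std.error)
  }
  expect_gte(hits, 20)  # joint 2-SE coverage runs near 93% per seed
})

test_that("rank agreement between DPI and SDPI degrades as index noise grows", {
  mean_rho <- function(noise_sd) {
    mean(sapply(1:5, function(s) {
      coh <- suppressWarnings(
        generate_cohort(n_subjects = 30, index_noise_sd = noise_sd,
                        seed = 40 + s))
      spearman_rank(coh$subjects$DPI, coh$subjects$SDPI)$rho
    }))
  }
  rhos <- sapply(c(1, 10, 40), mean_rho)
  expect_true(all(diff(rhos) < 0))
})
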