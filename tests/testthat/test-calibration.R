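test_that("the shipped calibration equations evaluate exactly", {
  vis <- default_calibration("visible")
  dis <- default_calibration("disclosed")
  expect_identical(apply_calibration(vis, 0), -7.5)
  expect_identical(apply_calibration(dis, 0), 40.62)
  expect_equal(apply_calibration(vis, 50), -7.5 + 1.14 * 50)
  expect_equal(apply_calibration(dis, 50), 40.62 + 0.44 * 50)
  flat <- calibration_model(12, 0, "visible")
  expect_equal(apply_calibration(flat, c(0, 37, 100)), rep(12, 3))
  # raw output is unclamped; the clamped accessor truncates to the scale
  expect_equal(apply_calibration(vis, 0, clamp = TRUE), 0)
  expect_equal(apply_calibration(vis, 120, clamp = TRUE), 100)
})

test_that("OLS refit recovers exact lines to machine precision", {
  on_line <- tibble::tibble(fraction_pct = c(0, 10, 35, 60, 90))
  on_line$full_mouth_index <- -7.5 + 1.14 * on_line$fraction_pct
  m <- fit_calibration(on_line, "visible")
  expect_equal(coef(m), c(intercept = -7.5, slope = 1.14), tolerance = 1e-12)

  simple <- tibble::tibble(fraction_pct = c(0, 50, 100),
                           full_mouth_index = c(0, 50, 100))
  expect_equal(coef(fit_calibration(simple, "visible")),
               c(intercept = 0, slope = 1), tolerance = 1e-12)
})

test_that("noisy refit matches the closed-form normal equations", {
  # frozen: seed 7, x = seq(5, 95, length 10), y = 40.62 + 0.44 x + N(0, 2),
  # coefficients from sum-of-squares normal equations computed independently
  set.seed(7)
  x <- seq(5, 95, length.out = 10)
  y <- 40.62 + 0.44 * x + rnorm(10, 0, 2)
  m <- fit_calibration(tibble::tibble(fraction_pct = x, full_mouth_index = y),
                       "disclosed")
  expect_equal(unname(coef(m)), c(39.9211658391, 0.4581357095),
               tolerance = 1e-9)
})

test_that("apply then fit is the identity on noise-free generated pairs", {
  set.seed(31)
  for (i in 1:10) {
    truth <- calibration_model(runif(1, -20, 50), runif(1, 0.1, 2), "visible")
    f <- runif(8, 0, 80)
    pairs <- tibble::tibble(fraction_pct = f,
                            full_mouth_index = apply_calibration(truth, f))
    m <- fit_calibration(pairs, "visible")
    expect_equal(coef(m), coef(truth), tolerance = 1e-9)
  }
})

test_that("degenerate calibration inputs are rejected", {
  two <- tibble::tibble(fraction_pct = c(0, 1), full_mouth_index = c(0, 1))
  expect_error(fit_calibration(two, "visible"), "at least 3")
  flat <- tibble::tibble(fraction_pct = rep(5, 4), full_mouth_index = 1:4)
  expect_error(fit_calibration(flat, "visible"), "identical")
  expect_error(calibration_model(Inf, 1, "visible"), "finite")
})

test_that("calibration models round-trip through JSON and tidy/glance", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.json")
  write_calibration(default_calibration("disclosed"), path)
  back <- read_calibration(path)
  expect_equal(back$intercept, 40.62)
  expect_equal(back$slope, 0.44)
  expect_equal(back$mode, "disclosed")

  pairs <- tibble::tibble(fraction_pct = c(0, 20, 40, 80),
                          full_mouth_index = c(2, 21, 39, 82))
  m <- fit_calibration(pairs, "visible")
  td <- tidy(m)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(m)
  expect_equal(gl$nobs, 4L)
  expect_gt(gl$r.squared, 0.99)
  expect_s3_class(autoplot(m), "ggplot")
})
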