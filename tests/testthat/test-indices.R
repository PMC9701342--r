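test_that("index arithmetic is exact on enumerated surface tables", {
  expect_equal(compute_index(enumerated_records(0), FALSE)$value_pct, 0)
  expect_equal(compute_index(enumerated_records(112), FALSE)$value_pct, 100)
  quarter <- compute_index(enumerated_records(28), FALSE)
  expect_equal(quarter$value_pct, 25)
  expect_equal(quarter$n_surfaces, 112L)
  expect_equal(quarter$n_positive, 28L)
  # exact rational value for an awkward denominator (a missing tooth)
  recs <- enumerated_records(28)
  recs <- recs[recs$tooth != 16, ]
  v <- compute_index(recs, FALSE)
  expect_equal(v$n_surfaces, 108L)
  expect_equal(v$value_pct, 100 * v$n_positive / 108)
})

test_that("anterior scope restricts to the twelve incisors and canines", {
  expect_setequal(anterior_teeth(),
                  c(13, 12, 11, 21, 22, 23, 33, 32, 31, 41, 42, 43))
  recs <- tibble::tibble(
    tooth = c(16L, 23L, rep(c(11L, 12L, 13L, 21L), 2), 36L, 46L, 47L, 44L, 45L),
    surface = c("buccal", "buccal", rep(c("mesial", "distal"), each = 4),
                rep("lingual", 5)),
    plaque_present = TRUE, disclosed = FALSE)
  ant <- anterior_subset(recs)
  expect_equal(nrow(ant), 9L)
  expect_true(all(ant$tooth %in% anterior_teeth()))
  expect_false(16 %in% ant$tooth)
  # the two code paths agree: subset-then-compute vs scope = "anterior"
  a <- compute_index(ant, FALSE, scope = "full_mouth")$value_pct
  b <- compute_index(recs, FALSE, scope = "anterior")$value_pct
  expect_equal(a, b)
})

test_that("the index is invariant to record order and split by disclosed flag", {
  set.seed(5)
  recs <- enumerated_records(40, disclosed = FALSE)
  recs$plaque_present <- sample(recs$plaque_present)
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(compute_index(recs, FALSE)$value_pct,
               compute_index(shuffled, FALSE)$value_pct)
  both <- dplyr::bind_rows(recs, enumerated_records(100, disclosed = TRUE))
  expect_equal(compute_index(both, TRUE)$value_pct, 100 * 100 / 112)
  expect_equal(compute_index(both, FALSE)$value_pct, 100 * 40 / 112)
})

test_that("invalid and duplicate records are rejected distinctly", {
  bad_tooth <- tibble::tibble(tooth = 18L, surface = "buccal",
                              plaque_present = TRUE, disclosed = FALSE)
  expect_error(compute_index(bad_tooth, FALSE), "FDI")
  bad_surface <- tibble::tibble(tooth = 11L, surface = "occlusal",
                                plaque_present = TRUE, disclosed = FALSE)
  expect_error(compute_index(bad_surface, FALSE), "surface")
  dup <- tibble::tibble(tooth = c(11L, 11L), surface = "buccal",
                        plaque_present = c(TRUE, FALSE), disclosed = FALSE)
  expect_error(compute_index(dup, FALSE), "[Dd]uplicate")
  expect_error(compute_index(enumerated_records(5, disclosed = FALSE), TRUE),
               "No disclosed")
  # same (tooth, surface) under different disclosed flags is legitimate
  two_flags <- dplyr::bind_rows(enumerated_records(5, FALSE),
                                enumerated_records(7, TRUE))
  expect_silent(compute_index(two_flags, TRUE))
})

test_that("surface-record CSVs enforce the strict header and round-trip", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(n_subjects = 4, seed = 12)
  paths <- write_cohort(coh, dir)
  back <- read_surface_records(paths[["records"]])
  expect_equal(nrow(back), nrow(coh$records))
  expect_type(back$plaque_present, "logical")
  per_subject <- compute_index(back, FALSE)
  expect_equal(nrow(per_subject), 4L)

  bad <- file.path(dir, "bad.csv")
  writeLines(c("id,tooth,surface,plaque_present,disclosed",
               "S1,11,buccal,1,0"), bad)
  suppressWarnings(expect_error(read_surface_records(bad), "header"))
})

test_that("mean paired index difference is linear arithmetic", {
  expect_equal(mean_index_difference(c(3, 4, 5), c(3, 4, 5)), 0)
  expect_equal(mean_index_difference(c(10, 20), c(50, 52)), 36)
  set.seed(6)
  a <- runif(20, 0, 100)
  b <- runif(20, 0, 100)
  expect_equal(mean_index_difference(a, b), mean(b) - mean(a))
  expect_error(mean_index_difference(1:3, 1:4), "equal-length")
})
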