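test_that("binary labels follow the grade rule and invalid grades are rejected", {
  p2 <- make_patient("a", 2L, 2015L)
  p4 <- make_patient("b", 4L, 2018L)
  expect_identical(p2$binary_label, 0L)
  expect_identical(p4$binary_label, 1L)
  expect_error(make_patient("c", 5L, 2015L), "1\\.\\.4")
  expect_error(patient("d", 1L, 2015L, list()), "no images")
  # one-directional noise invariant at the image level
  expect_error(image_sample("a", observed_label = 0, pixels = tiny_pixels(),
                            true_label = 1), "one-directional")
})

test_that("manifest read rejects invalid grades naming the row", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(patient_id = c("a", "b"), fuhrman_grade = c(2L, 5L),
                       acquisition_year = 2015L, image_path = "x.png"),
            path, row.names = FALSE)
  expect_error(read_manifest(path), "row 2")
  expect_error(read_manifest(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("manifest round-trip is lossless for all fields", {
  coh <- small_synth_cohort(seed = 42, n = 8L)
  dir <- withr::local_tempdir()
  write_manifest(coh, file.path(dir, "m.csv"))
  coh2 <- read_manifest(file.path(dir, "m.csv"))
  expect_identical(n_patients(coh2), n_patients(coh))
  expect_identical(n_images(coh2), n_images(coh))
  for (field in c("patient_id", "fuhrman_grade", "binary_label",
                  "acquisition_year")) {
    expect_identical(lapply(coh2$patients, `[[`, field),
                     lapply(coh$patients, `[[`, field))
  }
  tl <- function(cc) unlist(lapply(cc$patients, function(p)
    vapply(p$images, function(im) im$true_label, integer(1))))
  expect_identical(tl(coh2), tl(coh))
  expect_identical(lapply(coh2$patients, `[[`, "covariates"),
                   lapply(coh$patients, `[[`, "covariates"))
  # pixels survive the 8-bit PNG round trip to quantisation accuracy
  px1 <- load_pixels(coh$patients[[1]]$images[[1]])
  px2 <- load_pixels(coh2$patients[[1]]$images[[1]])
  expect_equal(dim(px1)[1:2], dim(px2)[1:2])
  expect_lt(max(abs(px1[, , 1] - px2[, , 1])), 1 / 254)
})

test_that("an empty cohort writes a header-only manifest", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(cohort(list(), "empty"), path)
  df <- read.csv(path)
  expect_identical(nrow(df), 0L)
  expect_true(all(c("patient_id", "fuhrman_grade") %in% names(df)))
  expect_identical(n_patients(read_manifest(path)), 0L)
})

test_that("temporal_split is an order-preserving exhaustive partition", {
  coh <- small_synth_cohort(seed = 9, n = 30L)
  years <- vapply(coh$patients, `[[`, integer(1), "acquisition_year")
  for (cutoff in c(min(years) - 1L, 2015L, 2018L, max(years) + 1L)) {
    parts <- temporal_split(coh, cutoff)
    expect_identical(n_patients(parts$development) +
                       n_patients(parts$validation), n_patients(coh))
    ids_dev <- vapply(parts$development$patients, `[[`, character(1),
                      "patient_id")
    ids_val <- vapply(parts$validation$patients, `[[`, character(1),
                      "patient_id")
    expect_length(intersect(ids_dev, ids_val), 0)
    expect_true(all(vapply(parts$development$patients, `[[`, integer(1),
                           "acquisition_year") < cutoff))
    expect_true(all(vapply(parts$validation$patients, `[[`, integer(1),
                           "acquisition_year") >= cutoff))
    # order preserved within each part
    all_ids <- vapply(coh$patients, `[[`, character(1), "patient_id")
    expect_identical(ids_dev, all_ids[all_ids %in% ids_dev])
    expect_identical(ids_val, all_ids[all_ids %in% ids_val])
  }
  everything <- temporal_split(coh, max(years) + 1L)
  expect_identical(n_patients(everything$validation), 0L)
})

test_that("cohort_stats reproduces half-up percentages on known compositions", {
  st <- cohort_stats(make_counts_cohort(n_low = 354L, n_high = 238L,
                                        n_male = 374L))
  expect_identical(st$n_patients, 592L)
  expect_equal(st$sex$percent[st$sex$level == "male"], 63.2)
  expect_equal(st$binary_label$percent, c(59.8, 40.2))
  expect_equal(sum(st$binary_label$percent), 100, tolerance = 0.1)

  st_val <- cohort_stats(make_counts_cohort(n_low = 76L, n_high = 38L))
  expect_equal(st_val$binary_label$percent[1], 66.7)

  one <- cohort_stats(cohort(list(make_patient("x", 1L, 2015L))))
  expect_equal(one$binary_label$percent[1], 100.0)
  expect_error(cohort_stats(cohort(list(), "e")), "empty")
})

test_that("binary-label percentages sum to ~100 for random compositions", {
  set.seed(77)
  for (r in 1:20) {
    n_low <- sample(1:50, 1); n_high <- sample(1:50, 1)
    st <- cohort_stats(make_counts_cohort(n_low, n_high))
    expect_equal(sum(st$binary_label$percent), 100, tolerance = 0.1)
    expect_identical(st$binary_label$count, c(n_low, n_high))
  }
})
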