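test_that("phantom generation is a pure function of (config, seed)", {
  cfg <- tiny_phantom_config()
  a <- generate_phantom(cfg, 7)
  b <- generate_phantom(cfg, 7)
  expect_identical(a, b)
  d <- generate_phantom(cfg, 8)
  expect_false(identical(a$pet$data, d$pet$data))
})

test_that("lesion_rate = 0 gives lesion-free phantoms", {
  cfg <- tiny_phantom_config(lesion_rate = 0)
  ph <- generate_phantom(cfg, 3)
  expect_false(any(ph$lesion_mask))
  expect_length(ph$lesions, 0)
})

test_that("noiseless lesion intensities honour the configured range", {
  cfg <- tiny_phantom_config(lesion_intensity_range = c(3, 5), noise_sd = 0)
  b <- cfg$background_uptake
  hits <- 0L
  for (s in 1:12) {
    ph <- generate_phantom(cfg, s)
    if (!length(ph$lesions)) next
    hits <- hits + 1L
    vals <- ph$pet$data[ph$lesion_mask]
    expect_true(all(vals >= 3 * b - 1e-12 & vals <= 5 * b + 1e-12))
    # placement records agree with the rendered voxels
    recorded <- vapply(ph$lesions, `[[`, 0, "intensity")
    expect_true(all(vals %in% recorded))
    expect_true(all(vals > b))          # every lesion voxel above background
  }
  expect_gt(hits, 3)
})

test_that("noiseless renders have exact background outside the body and hot organs", {
  cfg <- tiny_phantom_config(noise_sd = 0)
  ph <- generate_phantom(cfg, 5)
  expect_true(all(ph$pet$data[!ph$body] == 0))
  expect_true(all(ph$ct$data[!ph$body] == 0))
  organ_mean <- mean(ph$pet$data[ph$organ_labels > 0])
  rest_mean <- mean(ph$pet$data[ph$body & ph$organ_labels == 0])
  expect_gt(organ_mean, rest_mean)
  # organs are visible at the same coordinates in the anatomical channel
  for (o in seq_along(ph$organs)) {
    inside <- ph$organ_labels == o
    expect_true(all(ph$ct$data[inside] == 0.45 + 0.07 * o))
  }
  # lesions are functional-only: anatomical channel stays soft tissue there
  if (any(ph$lesion_mask))
    expect_true(all(ph$ct$data[ph$lesion_mask] == 0.30))
})

test_that("empirical lesion count matches the configured rate", {
  cfg <- tiny_phantom_config(lesion_rate = 2)
  n <- vapply(1:100, function(s) length(generate_phantom(cfg, 100 + s)$lesions), 0)
  expect_gt(mean(n), 2 * 0.7)
  expect_lt(mean(n), 2 * 1.3)
})

test_that("a shape too small for the requested organs errors", {
  expect_error(generate_phantom(phantom_config(shape = c(8, 8, 8), n_organs = 3)),
               "too small")
  expect_error(phantom_config(shape = c(4, 16, 16)), ">= 8")
  expect_error(phantom_config(lesion_intensity_range = c(5, 3)), "lo <= hi")
})

test_that("dataset splits honour sizes, seeds and the contamination switch", {
  cfg <- tiny_phantom_config()
  ds <- make_dataset(cfg, n_train = 60, n_val = 11, n_test = 12, seed = 50)
  expect_length(ds$train, 60)
  expect_length(ds$val, 11)
  expect_length(ds$test, 12)
  seeds <- unlist(lapply(ds, function(split) vapply(split, `[[`, 0L, "seed")))
  expect_length(unique(seeds), 83)          # disjoint seeds across splits
  expect_true(any(vapply(ds$train, function(s) any(s$lesion_mask), NA)))
  ds2 <- make_dataset(cfg, n_train = 60, n_val = 11, n_test = 12, seed = 50)
  expect_identical(ds, ds2)
  clean <- make_dataset(cfg, n_train = 5, n_val = 2, n_test = 2,
                        contaminate_train = FALSE, seed = 50)
  expect_false(any(vapply(clean$train, function(s) any(s$lesion_mask), NA)))
  expect_equal(nrow(dataset_manifest(ds)), 83)
})

test_that("NIfTI round-trip preserves voxels, spacing and modality", {
  ph <- generate_phantom(tiny_phantom_config(spacing = c(2, 2, 3)), 9)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(ph$pet, f)
  back <- read_nifti(f)
  expect_lt(max(abs(back$data - ph$pet$data)), 1e-6)
  expect_equal(back$spacing, c(2, 2, 3))
  expect_identical(back$modality, "functional")
  write_nifti(ph$ct, f)
  expect_identical(read_nifti(f)$modality, "anatomical")
})

test_that("a non-NIfTI file raises a parse error, not a crash", {
  f <- withr::local_tempfile(fileext = ".nii")
  writeLines("definitely not a nifti header", f)
  expect_error(read_nifti(f), "NIfTI")
})

test_that("volume constructor enforces its invariants", {
  expect_error(volume(array(1, c(4, 8, 8))), ">= 8")
  expect_error(volume(array(c(NA, rep(1, 511)), c(8, 8, 8))), "finite")
  expect_error(volume(array(-1, c(8, 8, 8)), modality = "functional"),
               "non-negative")
  expect_silent(volume(array(-1, c(8, 8, 8)), modality = "anatomical"))
})
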