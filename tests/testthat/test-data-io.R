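test_that("NIfTI round-trip preserves values, spacing and labels", {
  d <- withr::local_tempdir()
  arr <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  vol <- mm_volume(arr, spacing = c(1.5, 1.0, 2.0))
  p <- file.path(d, "vol.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(as.numeric(back$data), as.numeric(arr))
  expect_equal(back$spacing, c(1.5, 1.0, 2.0))

  lab <- label_volume(array(sample(c(0L, 1L, 2L, 4L), 64, TRUE), c(4, 4, 4)),
                      spacing = c(1, 1, 1))
  lp <- file.path(d, "lab.nii.gz")
  write_volume(lab, lp)
  lback <- read_volume(lp, kind = "label")
  expect_identical(lback$data, lab$data)
  expect_equal(lback$spacing, c(1, 1, 1))
})

test_that("label validation rejects values outside {0,1,2,4}", {
  d <- withr::local_tempdir()
  bad <- array(c(0L, 1L, 3L, 2L), c(1, 2, 2))
  expect_error(label_volume(bad), "3")
  # a 3D file containing an invalid value fails at load time too
  img <- RNifti::asNifti(array(c(0, 1, 3, 4), c(1, 2, 2)))
  RNifti::writeNifti(img, file.path(d, "bad.nii.gz"))
  expect_error(read_volume(file.path(d, "bad.nii.gz"), kind = "label"), "3")
  expect_error(read_volume(file.path(d, "missing.nii.gz")), "not found")
})

test_that("extract_slices honours keep_empty and records provenance", {
  nz <- 8
  vol <- mm_volume(array(rnorm(nz * 6 * 6 * 2), c(nz, 6, 6, 2)))
  labs <- array(0L, c(nz, 6, 6))
  tumor_planes <- c(2, 5, 7)
  for (z in tumor_planes) labs[z, 3, 3] <- 2L
  lab <- label_volume(labs)

  all_slices <- extract_slices(vol, lab, keep_empty = TRUE, volume_id = "v1")
  expect_length(all_slices, nz)
  expect_equal(vapply(all_slices, function(s) s$slice_index, integer(1)), 1:nz)
  expect_equal(all_slices[[3]]$image, array(vol$data[3, , , ], c(6, 6, 2)))

  # oracle: brute-force count of nonempty planes
  nonempty <- sum(vapply(seq_len(nz), function(z) any(labs[z, , ] != 0), logical(1)))
  kept <- extract_slices(vol, lab, keep_empty = FALSE)
  expect_length(kept, nonempty)
  expect_length(kept, length(tumor_planes))

  empty_lab <- label_volume(array(0L, c(nz, 6, 6)))
  expect_length(extract_slices(vol, empty_lab, keep_empty = FALSE), 0)

  small <- label_volume(array(0L, c(2, 6, 6)))
  expect_error(extract_slices(vol, small), "differ")
})

test_that("intensity standardization matches its definitions", {
  m <- matrix(c(0, 2, 4, 6), 2, 2)
  expect_equal(normalize_intensity(m, "minmax"), matrix(c(0, 1 / 3, 2 / 3, 1), 2, 2))
  expect_equal(normalize_intensity(matrix(5, 3, 3), "zscore"), matrix(0, 3, 3))
  x <- array(rnorm(16 * 16 * 3, mean = 7, sd = 3), c(16, 16, 3))
  z <- normalize_intensity(x, "zscore")
  for (c in 1:3) {
    expect_lt(abs(mean(z[, , c])), 1e-6)
    expect_lt(abs(sd(z[, , c]) - 1), 1e-6)
  }
})

test_that("resampling preserves shapes and the mask label set", {
  img <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  msk <- matrix(sample(c(0L, 2L), 36, TRUE), 6, 6)
  same <- resample_to(img, msk, c(6, 6))
  expect_identical(same$mask, msk)
  expect_equal(same$image, img)

  up <- resample_to(img, msk, c(12, 12))
  expect_true(all(up$mask %in% c(0L, 2L)))
  expect_equal(dim(up$image), c(12L, 12L, 2L))

  checker <- matrix(c(1, 0, 0, 1), 2, 2)
  down <- resample_to(resample_to(checker, NULL, c(4, 4))$image, NULL, c(2, 2))
  expect_equal(dim(down$image), c(2L, 2L))
  expect_error(resample_to(img, msk, c(0, 4)), "positive")
})

test_that("region derivation follows the BraTS mapping and nests", {
  one <- function(v) matrix(c(v, 0L, 0L, 0L), 2, 2)
  r4 <- derive_regions(one(4L))
  expect_true(r4$wt[1, 1] && r4$tc[1, 1] && r4$et[1, 1])
  r2 <- derive_regions(one(2L))
  expect_true(r2$wt[1, 1] && !r2$tc[1, 1] && !r2$et[1, 1])
  r1 <- derive_regions(one(1L))
  expect_true(r1$wt[1, 1] && r1$tc[1, 1] && !r1$et[1, 1])
  expect_error(derive_regions(one(5L)), "5")

  set.seed(3)
  for (i in 1:25) {
    labs <- matrix(sample(c(0L, 1L, 2L, 4L), 64, TRUE), 8, 8)
    r <- derive_regions(labs)
    expect_true(all(r$tc[r$et]))
    expect_true(all(r$wt[r$tc]))
  }
})

test_that("augmentation transforms image and mask identically", {
  set.seed(9)
  s <- generate_phantom(tiny_phantom_spec(), seed = 21)
  # involutions
  for (op in c("hflip", "vflip")) {
    twice <- augment_sample(augment_sample(s, op), op)
    expect_identical(twice$image, s$image)
    expect_identical(twice$mask, s$mask)
  }
  r2twice <- augment_sample(augment_sample(s, "rotate90", k = 2), "rotate90", k = 2)
  expect_identical(r2twice$mask, s$mask)
  expect_identical(r2twice$image, s$image)

  # right-angle rotation preserves foreground counts exactly
  r1 <- augment_sample(s, "rotate90", k = 1)
  expect_identical(sum(r1$mask > 0), sum(s$mask > 0))
  expect_identical(as.integer(table(factor(r1$mask, levels = c(0, 1, 2, 4)))),
                   as.integer(table(factor(s$mask, levels = c(0, 1, 2, 4)))))
  # rotation moves image pixels with the mask: a marked corner travels along
  expect_equal(r1$image[1, 1, 1], s$image[1, dim(s$image)[2], 1])

  sc <- augment_sample(s, "scale", f = 2.0)
  expect_equal(dim(sc$image), dim(s$image))
  expect_true(all(sc$mask %in% c(0L, 1L, 2L, 4L)))
  expect_error(augment_sample(s, "scale", f = 0), "> 0")
})

test_that("manifest loading reassembles per-modality files", {
  d <- withr::local_tempdir()
  arr <- array(rnorm(2 * 4 * 4), c(2, 4, 4, 1))
  mods <- list(FLAIR = arr, T1 = arr * 2)
  paths <- list()
  for (nm in names(mods)) {
    p <- file.path(d, paste0(nm, ".nii.gz"))
    write_volume(mm_volume(mods[[nm]]), p)
    paths[[nm]] <- basename(p)
  }
  lab <- label_volume(array(c(rep(0L, 15), 2L, rep(0L, 16)), c(2, 4, 4)))
  write_volume(lab, file.path(d, "seg.nii.gz"))
  manifest <- file.path(d, "manifest.json")
  jsonlite::write_json(list(list(id = "case1", image = paths, label = "seg.nii.gz")),
                       manifest, auto_unbox = TRUE)
  samples <- load_dataset(manifest, keep_empty = FALSE)
  expect_length(samples, 1)
  expect_equal(dim(samples[[1]]$image)[3], 2L)
  expect_equal(samples[[1]]$image[, , 2], 2 * samples[[1]]$image[, , 1])
})
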