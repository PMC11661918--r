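# Synthetic fixture generation, PNG dataset layout and NIfTI slicing.

test_that("generation is a pure function of (seed, index)", {
  spec <- fixture_spec(size = 64, n_classes = 4, seed = 9)
  a <- generate_sample(spec, 3)
  b <- generate_sample(spec, 3)
  expect_identical(a, b)
  expect_false(identical(a$mask, generate_sample(spec, 4)$mask))
  expect_true(all(a$mask >= 0 & a$mask < 4))
  expect_equal(dim(a$image), c(64L, 64L, 3L))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # interleaved generation does not disturb per-sample determinism
  c1 <- generate_sample(spec, 1)
  generate_sample(spec, 2)
  expect_identical(generate_sample(spec, 1), c1)
})

test_that("noise-free intensities are a deterministic function of the label", {
  spec <- fixture_spec(size = 64, n_classes = 5, noise_sd = 0, seed = 2)
  s <- generate_sample(spec, 1)
  plane <- s$image[, , 1]
  for (cls in sort(unique(as.vector(s$mask)))) {
    vals <- unique(plane[s$mask == cls])
    expect_length(vals, 1)
    expect_equal(vals, (cls + 0.5) / 5)
  }
  # channels are replicated
  expect_equal(s$image[, , 1], s$image[, , 2])
})

test_that("datasets round-trip through PNG files and detect corruption", {
  spec <- fixture_spec(size = 32 * 2, n_classes = 4, seed = 5)
  dir <- tempfile("ds")
  write_dataset(spec, 4, dir)
  expect_length(list.files(file.path(dir, "images")), 4)
  expect_length(list.files(file.path(dir, "masks")), 4)
  ds <- read_dataset(dir, 4)
  expect_length(ds, 4)
  for (i in 1:4) {
    ref <- generate_sample(spec, i)
    expect_identical(ds[[i]]$mask, ref$mask)          # masks exact
    expect_lt(max(abs(ds[[i]]$image - ref$image)), 1 / 255)  # 8-bit images
  }
  # unpaired file detected
  file.remove(file.path(dir, "masks", "sample_002.png"))
  expect_error(read_dataset(dir, 4), "unpaired")
  # out-of-range labels detected
  dir2 <- tempfile("ds")
  write_dataset(spec, 1, dir2)
  expect_error(read_dataset(dir2, 2), "n_classes")
})

test_that("png codec agrees with an independent reference encoder", {
  # bytes produced by Pillow, frozen in helper-fixtures.R
  rgb_path <- tempfile(fileext = ".png")
  writeBin(hex_to_raw(fixture_png_rgb_hex), rgb_path)
  img <- read_image_png(rgb_path)
  expect_equal(dim(img), c(2L, 3L, 3L))
  vals <- round(img * 255)
  expect_equal(vals[1, 1, ], c(0, 10, 20))
  expect_equal(vals[2, 3, ], c(150, 160, 170))
  mask_path <- tempfile(fileext = ".png")
  writeBin(hex_to_raw(fixture_png_mask_hex), mask_path)
  mask <- read_mask_png(mask_path)
  expect_equal(mask, matrix(c(0L, 3L, 0L, 1L,
                              1L, 2L, 0L, 2L,
                              2L, 1L, 3L, 3L), 4, 3))
})

test_that("augmentation keeps image and mask aligned", {
  # with zero noise the image is an exact function of the label map, so any
  # misalignment between the two transforms would break that relation
  spec <- fixture_spec(size = 64, n_classes = 4, noise_sd = 0, seed = 13)
  s <- generate_sample(spec, 1)
  set.seed(77)
  hist_before <- tabulate(s$mask + 1L, 4)
  for (t in 1:20) {
    out <- augment(s$image, s$mask)
    # per-class pixel counts are preserved (pure pixel permutation)
    expect_equal(tabulate(out$mask + 1L, 4), hist_before)
    # labels present are unchanged
    expect_setequal(unique(as.vector(out$mask)), unique(as.vector(s$mask)))
    # alignment: intensity still equals the per-label intensity everywhere
    expect_equal(out$image[, , 1], (out$mask + 0.5) / 4, tolerance = 1e-12)
  }
  # a double horizontal flip is the identity
  flip_h <- function(m) m[, ncol(m):1]
  expect_identical(flip_h(flip_h(s$mask)), s$mask)
})

test_that("nifti volumes round-trip and slices pair with labels", {
  vol <- array(seq_len(6 * 6 * 4) / 10, c(6, 6, 4))
  lab <- array(sample(0:2, 6 * 6 * 4, TRUE), c(6, 6, 4))
  vp <- tempfile(fileext = ".nii")
  lp <- tempfile(fileext = ".nii.gz")
  write_nifti(vol, vp, datatype = 16L)
  write_nifti(lab, lp, datatype = 4L)
  expect_equal(read_nifti(vp), vol, tolerance = 1e-6)   # float32 storage
  expect_equal(read_nifti(lp), array(as.numeric(lab), dim(lab)))
  sl <- read_nifti_slices(vp, lp)
  expect_length(sl, 4)                                  # one per axial slice
  expect_equal(dim(sl[[1]]$image), c(6L, 6L, 3L))
  expect_true(all(vapply(sl, function(s) all(s$mask == round(s$mask)), TRUE)))
  rng <- range(do.call(c, lapply(sl, function(s) s$image)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # volume/label dimension mismatch rejected
  vp2 <- tempfile(fileext = ".nii")
  write_nifti(vol[, , 1:3], vp2)
  expect_error(read_nifti_slices(vp2, lp), "differ")
})

test_that("the nifti reader decodes files written by the reference library", {
  # bytes produced by nibabel, frozen in helper-fixtures.R
  path <- tempfile(fileext = ".nii")
  writeBin(hex_to_raw(fixture_nii_hex), path)
  vol <- read_nifti(path)
  expect_equal(dim(vol), c(2L, 3L, 4L))
  expect_equal(as.vector(vol), (seq_len(24) - 1) / 4, tolerance = 1e-7)
})
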