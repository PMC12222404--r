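test_that("NIfTI round trip preserves values and grid metadata", {
  set.seed(42)
  v <- volume3d(array(rnorm(8^3), c(8, 8, 8)),
                spacing = c(4.795, 4.795, 4.795),
                origin = c(-10.5, 20, 3.25))
  path <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  expect_volumes_equal(v, r, meta_tol = 1e-7)
  expect_equal(r$spacing, c(4.795, 4.795, 4.795), tolerance = 1e-7)
})

test_that("MetaImage round trip preserves values and grid metadata", {
  set.seed(7)
  v <- volume3d(array(runif(6 * 7 * 8, 0, 400), c(6, 7, 8)),
                spacing = c(4.418, 4.418, 4.418), origin = c(1, -2, 3))
  path <- file.path(tempdir(), "rt.mha")
  write_volume(v, path)
  r <- read_volume(path)
  expect_volumes_equal(v, r)
  # dose maps with values above 400 Gy are not clipped on IO
  expect_equal(max(r$values), max(v$values))
})

test_that("integer label volumes survive IO exactly", {
  lab <- array(sample(0:4, 5^3, replace = TRUE), c(5, 5, 5))
  v <- volume3d(lab + 0, spacing = c(2, 2, 2))
  for (ext in c("nii.gz", "mha")) {
    path <- file.path(tempdir(), paste0("lab.", ext))
    write_volume(v, path)
    r <- read_volume(path)
    expect_identical(as.integer(r$values), as.integer(lab))
  }
})

test_that("reading rejects non-3D payloads and bad paths", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  img2d <- RNifti::asNifti(matrix(1:4, 2, 2))
  p <- file.path(tempdir(), "flat.nii.gz")
  RNifti::writeNifti(img2d, p)
  expect_error(read_volume(p), "3D")
  expect_error(write_volume(volume3d(array(0, c(2, 2, 2))),
                            file.path(tempdir(), "x.bmp")), "format")
  expect_error(write_volume(volume3d(array(0, c(2, 2, 2))),
                            "/nonexistent-dir/x.nii.gz"), "directory")
})

test_that("volume3d enforces its invariants", {
  expect_error(volume3d(array(NA_real_, c(2, 2, 2))), "finite")
  expect_error(volume3d(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(volume3d(matrix(0, 2, 2)), "3D")
})

test_that("resampling a constant field in continuous mode stays constant", {
  v <- volume3d(array(7.5, c(16, 16, 16)), spacing = rep(4.795, 3))
  r <- resample_to_grid(v, 4.418, "continuous")
  expect_lt(max(abs(r$values - 7.5)), 1e-12)
  # identical spacing is the identity
  expect_identical(resample_to_grid(v, 4.795)$values, v$values)
  expect_error(resample_to_grid(v, -1), "positive")
})

test_that("nearest-neighbour resampling introduces no new labels", {
  set.seed(3)
  lab <- array(sample(c(0, 1, 3), 12^3, replace = TRUE), c(12, 12, 12))
  v <- volume3d(lab, spacing = rep(4, 3))
  r <- resample_to_grid(v, 3, "nearest")
  expect_true(all(unique(as.numeric(r$values)) %in% c(0, 1, 3)))
})

test_that("extensive resampling approximately preserves the total", {
  set.seed(5)
  v <- volume3d(array(runif(20^3), c(20, 20, 20)), spacing = rep(4.795, 3))
  r <- resample_to_grid(v, 3.2, "continuous", extensive = TRUE)
  expect_lt(abs(sum(r$values) - sum(v$values)) / sum(v$values), 0.01)
})

test_that("mask set algebra survives nearest-neighbour resampling", {
  ph <- build_phantom(test_recipe())
  enc <- encode_labels(ph$masks)
  v <- volume3d(enc$label_volume + 0, spacing = ph$masks$spacing)
  r <- resample_to_grid(v, 6.5, "nearest")
  dec <- decode_labels(array(as.integer(r$values), dim(r$values)),
                       enc$label_table, spacing = rep(6.5, 3))
  m <- dec$masks
  expect_identical(m$wnl, m$wl & !m$tumour)
  expect_false(any(m$tumour & !m$wl))
})

test_that("derive_body_mask recovers a solid sphere and picks the largest blob", {
  d <- c(24, 24, 24)
  sphere <- array(0, d)
  ctr <- c(12.5, 12.5, 12.5)
  idx <- which(array(TRUE, d))
  pos <- arrayInd(idx, d)
  r2 <- rowSums((sweep(pos, 2, ctr))^2)
  sphere[idx[r2 <= 8^2]] <- 10
  v <- volume3d(sphere, spacing = rep(2, 3))
  m <- derive_body_mask(v, 0.01)
  oracle <- array(FALSE, d); oracle[idx[r2 <= 8^2]] <- TRUE
  # closing may add no voxels to a convex solid
  expect_identical(m, oracle)

  # two blobs: keep only the big one
  two <- sphere
  two[2:3, 2:3, 2:3] <- 10
  m2 <- derive_body_mask(volume3d(two, spacing = rep(2, 3)), 0.01)
  expect_false(any(m2[2:3, 2:3, 2:3]))
  expect_true(all(m2[idx[r2 <= 7^2]]))

  expect_warning(derive_body_mask(volume3d(array(0, c(4, 4, 4)))), "empty")
})
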