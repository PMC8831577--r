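test_that("DICOM series round-trips phantom volumes bit-exactly", {
  ph <- generate_phantom(small_spec(), seed = 3)
  d <- withr::local_tempdir()
  write_ct_series(ph$volume, d)
  v2 <- load_ct_series(d)
  expect_identical(v2$voxels, ph$volume$voxels)
  expect_equal(v2$spacing, ph$volume$spacing)
})

test_that("rescale slope/intercept maps stored values to HU", {
  # stored 100 with slope 1 / intercept -1024 must read back as -924 HU
  d <- withr::local_tempdir()
  px <- matrix(100L, 8, 8)
  for (i in 1:3) {
    eatseg:::write_dicom_file(
      file.path(d, sprintf("s%d.dcm", i)), pixels = px,
      pixel_spacing = c(0.7, 0.7), slice_thickness = 2.5,
      position = c(0, 0, (i - 1) * 2.5), instance = i,
      series_uid = "1.2.3.4", slope = 1, intercept = -1024)
  }
  v <- load_ct_series(d)
  expect_true(all(v$voxels == -924))
})

test_that("slice ordering is a function of position, not file order", {
  ph <- generate_phantom(small_spec(), seed = 5)
  d1 <- withr::local_tempdir()
  write_ct_series(ph$volume, d1)
  # re-present the same files under shuffled names
  d2 <- withr::local_tempdir()
  files <- list.files(d1, full.names = TRUE)
  set.seed(1)
  shuffled <- sample(seq_along(files))
  for (i in seq_along(files)) {
    file.copy(files[shuffled[i]], file.path(d2, sprintf("f%02d.dcm", i)))
  }
  v1 <- load_ct_series(d1)
  v2 <- load_ct_series(d2)
  expect_identical(v2$voxels, v1$voxels)

  # explicit sort-by-position oracle: slice i must hold the data written
  # at z position (i-1)*dz regardless of presentation order
  z <- sapply(list.files(d1, full.names = TRUE),
              function(f) eatseg:::read_dicom_file(f)$position[3])
  expect_identical(order(z), seq_along(z))
})

test_that("our DICOM encoding agrees with an independent reader", {
  set.seed(11)
  v <- ct_volume(array(round(rnorm(12 * 12 * 3, -100, 150)),
                       dim = c(12, 12, 3)),
                 spacing = c(0.8, 0.75, 2.5), scan_id = "xcheck")
  d <- withr::local_tempdir()
  write_ct_series(v, d)
  script <- file.path(d, "read.py")
  out_csv <- file.path(d, "out.csv")
  writeLines(c(
    "import pydicom, glob, sys",
    sprintf("files = sorted(glob.glob(r'%s/*.dcm'))", d),
    "ds = [pydicom.dcmread(f) for f in files]",
    "ds.sort(key=lambda s: float(s.ImagePositionPatient[2]))",
    "rows = []",
    "for s in ds:",
    "    hu = s.pixel_array * float(s.RescaleSlope) + float(s.RescaleIntercept)",
    "    rows.extend(hu.flatten(order='F').tolist())",
    sprintf("open(r'%s', 'w').write('\\n'.join(str(x) for x in rows) + '\\n')",
            out_csv)
  ), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  got <- as.numeric(readLines(out_csv))
  expect_equal(got, as.vector(v$voxels))
})

test_that("malformed series are rejected", {
  ph <- generate_phantom(small_spec(), seed = 1)
  d <- withr::local_tempdir()
  write_ct_series(ph$volume, d)
  # inject a slice from a different series
  eatseg:::write_dicom_file(
    file.path(d, "alien.dcm"), pixels = matrix(0L, 40, 40),
    pixel_spacing = c(0.7, 0.7), slice_thickness = 2.5,
    position = c(0, 0, 99), instance = 99, series_uid = "9.9.9")
  expect_error(load_ct_series(d), "mixed series")

  # non-uniform spacing beyond 1%
  d3 <- withr::local_tempdir()
  for (i in 1:4) {
    z <- c(0, 2.5, 5.0, 7.9)[i]  # last gap 2.9 mm vs 2.5 mm
    eatseg:::write_dicom_file(
      file.path(d3, sprintf("s%d.dcm", i)), pixels = matrix(0L, 8, 8),
      pixel_spacing = c(0.7, 0.7), slice_thickness = 2.5,
      position = c(0, 0, z), instance = i, series_uid = "1.2.3")
  }
  expect_error(load_ct_series(d3), "non-uniform")
})

test_that("mask NIfTI round trip is lossless and rejects non-binary files", {
  ph <- generate_phantom(small_spec(), seed = 2)
  f <- withr::local_tempfile(fileext = ".nii.gz")

  zero <- mask_volume(array(0L, dim = dim(ph$volume$voxels)),
                      spacing = ph$volume$spacing)
  save_mask(zero, f)
  expect_identical(load_mask(f, ph$volume)$voxels, zero$voxels)

  set.seed(4)
  rnd <- mask_volume(
    array(rbinom(prod(dim(ph$volume$voxels)), 1, 0.4),
          dim = dim(ph$volume$voxels)),
    spacing = ph$volume$spacing, label = "eat")
  save_mask(rnd, f)
  m2 <- load_mask(f, ph$volume, label = "eat")
  expect_identical(m2$voxels, rnd$voxels)
  expect_equal(m2$spacing, rnd$spacing)

  # a file containing a value of 2 must be rejected
  bad <- array(0L, dim = dim(ph$volume$voxels)); bad[1] <- 2L
  img <- RNifti::asNifti(bad)
  RNifti::pixdim(img) <- ph$volume$spacing
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f2, datatype = "uint8")
  expect_error(load_mask(f2, ph$volume), "non-binary")
})

test_that("crop_to_extent does index arithmetic correctly", {
  set.seed(9)
  v <- ct_volume(array(rnorm(6 * 6 * 10), dim = c(6, 6, 10)),
                 spacing = c(1, 1, 2.5))
  whole <- crop_to_extent(v, heart_extent(1, 10))
  expect_identical(whole$voxels, v$voxels)

  cropped <- crop_to_extent(v, heart_extent(3, 8))
  expect_equal(dim(cropped$voxels)[3], 6)
  expect_identical(cropped$voxels[, , 1], v$voxels[, , 3])
  expect_identical(cropped$voxels[, , 6], v$voxels[, , 8])
  expect_equal(cropped$spacing, v$spacing)

  expect_error(heart_extent(6, 5), "bottom <= top")
  expect_error(crop_to_extent(v, heart_extent(8, 12)), "exceeds")
  expect_error(heart_extent(1, 2), "at least 3")
})
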