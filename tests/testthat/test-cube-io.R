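# Data model, radiometric calibration, and file-format round trips.

test_that("transmittance calibration satisfies its defining identities", {
  white <- hsi_cube(array(100, c(3, 3, 4)))
  dark <- hsi_cube(array(10, c(3, 3, 4)))

  # raw == white -> all 1; raw == dark -> all 0; linear interpolation -> 0.25
  expect_equal(calibrate_transmittance(white, white, dark)$values,
               array(1, c(3, 3, 4)))
  expect_equal(calibrate_transmittance(dark, white, dark)$values,
               array(0, c(3, 3, 4)))
  quarter <- hsi_cube(dark$values + 0.25 * (white$values - dark$values))
  expect_equal(calibrate_transmittance(quarter, white, dark)$values,
               array(0.25, c(3, 3, 4)))
})

test_that("calibration is monotone, clamps, masks dead pixels, checks shape", {
  set.seed(42)
  white <- hsi_cube(array(runif(60, 90, 110), c(5, 4, 3)))
  dark <- hsi_cube(array(runif(60, 5, 15), c(5, 4, 3)))
  raw1 <- hsi_cube(array(runif(60, 10, 100), c(5, 4, 3)))
  raw2 <- hsi_cube(raw1$values + runif(60, 0, 5))   # elementwise >= raw1
  t1 <- calibrate_transmittance(raw1, white, dark)
  t2 <- calibrate_transmittance(raw2, white, dark)
  expect_true(all(t2$values >= t1$values))

  # raw far above white clamps at the ceiling
  hot <- hsi_cube(array(1e4, c(5, 4, 3)))
  expect_equal(max(calibrate_transmittance(hot, white, dark)$values), 1.2)
  expect_equal(
    max(calibrate_transmittance(hot, white, dark, clamp_max = 1)$values), 1)

  # white - dark below eps is masked to 0 and counted
  w2 <- white; w2$values[1, 1, 1] <- dark$values[1, 1, 1]
  out <- calibrate_transmittance(raw1, w2, dark)
  expect_equal(out$values[1, 1, 1], 0)
  expect_equal(out$meta$calibration$n_masked, 1L)

  expect_error(calibrate_transmittance(rand_cube(2, 2, 3), white, dark),
               "identical shapes")
})

test_that("cube invariants are enforced at construction", {
  expect_error(hsi_cube(array(1, c(2, 2, 3)), wavelengths = c(500, 490, 510)),
               "increasing")
  expect_error(hsi_cube(array(1, c(2, 2, 3)), wavelengths = c(500, 510)),
               "number of bands")
  expect_error(hsi_cube(array(c(1, NA), c(2, 2, 3))), "finite")
  expect_error(rgb_image(array(2, c(2, 2, 3))), "\\[0, 1\\]")
  expect_error(rgb_image(array(0.5, c(2, 2, 4))), "3 channels")
})

test_that("HDF5 round trip is bit-exact and ENVI round trip preserves all", {
  skip_if_not_installed("rhdf5")
  cube <- rand_cube(4, 4, 5, seed = 9)
  cube$meta$slide <- "demo"
  f <- tempfile(fileext = ".h5")
  write_cube(cube, f)
  back <- read_cube(f)
  expect_identical(back$values, cube$values)
  expect_equal(back$wavelengths, cube$wavelengths)
  expect_equal(back$meta$slide, "demo")

  fe <- tempfile(fileext = ".dat")
  write_cube(cube, fe)
  back_e <- read_cube(fe)
  expect_identical(back_e$values, cube$values)
  expect_equal(back_e$wavelengths, cube$wavelengths)
})

test_that("ENVI reader handles BIL/BIP interleaves and bad headers", {
  cube <- rand_cube(3, 5, 4, seed = 2)
  f <- tempfile(fileext = ".dat")
  write_cube(cube, f, format = "envi")
  hdr <- sub("\\.dat$", ".hdr", f)

  # rewrite the binary as BIL and patch the header
  v <- aperm(cube$values, c(2L, 3L, 1L))   # sample, band, line
  con <- file(f, "wb"); writeBin(as.vector(v), con, size = 8L); close(con)
  txt <- sub("interleave = bsq", "interleave = bil", readLines(hdr))
  writeLines(txt, hdr)
  expect_equal(read_cube(f)$values, cube$values)

  v <- aperm(cube$values, c(3L, 2L, 1L))   # band, sample, line
  con <- file(f, "wb"); writeBin(as.vector(v), con, size = 8L); close(con)
  txt <- sub("interleave = bil", "interleave = bip", readLines(hdr))
  writeLines(txt, hdr)
  expect_equal(read_cube(f)$values, cube$values)

  # non-monotone wavelength metadata must not build a cube
  txt <- readLines(hdr)
  txt <- sub("^wavelength = .*",
             sprintf("wavelength = { %s }",
                     paste(rev(cube$wavelengths), collapse = ", ")), txt)
  writeLines(txt, hdr)
  expect_error(read_cube(f), "increasing")
})

test_that("multi-page TIFF stack round-trips to float precision", {
  cube <- rand_cube(6, 5, 5, seed = 4, lo = 0, hi = 1.15)
  f <- tempfile(fileext = ".tif")
  write_cube(cube, f)
  back <- read_cube(f)
  expect_equal(dim(back$values), dim(cube$values))
  expect_equal(back$values, cube$values, tolerance = 1e-6)
  expect_equal(back$wavelengths, cube$wavelengths)

  # without the sidecar, the wavelength grid must come from the caller
  file.remove(paste0(f, ".json"))
  expect_error(read_cube(f), "wavelength")
  supplied <- read_cube(f, wavelengths = cube$wavelengths)
  expect_equal(supplied$wavelengths, cube$wavelengths)
})

test_that("patch sets round-trip through the HDF5 layout", {
  skip_if_not_installed("rhdf5")
  patches <- toy_patch_set(n = 3L)
  f <- tempfile(fileext = ".h5")
  write_patch_set(patches, f)
  back <- read_patch_set(f)
  expect_length(back, 3L)
  expect_identical(back[[2L]]$hr_hsi$values, patches[[2L]]$hr_hsi$values)
  expect_identical(back[[2L]]$lr_hsi$values, patches[[2L]]$lr_hsi$values)
  expect_identical(back[[2L]]$label, patches[[2L]]$label)
})

test_that("patch_pair enforces its consistency invariants", {
  hr <- rand_cube(8, 8, 3)
  lr <- box_downsample(hr, 4L)
  rgb <- rand_rgb(8, 8)
  expect_s3_class(patch_pair(hr, rgb, lr, label = 1L), "patch_pair")
  expect_error(patch_pair(hr, rand_rgb(6, 6), lr), "spatial dims")
  expect_error(patch_pair(hr, rgb, rand_cube(3, 3, 3)), "multiple")
  expect_error(patch_pair(hr, rgb, lr, label = 2), "label")
})
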