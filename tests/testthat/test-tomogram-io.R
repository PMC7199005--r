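test_that("constructor enforces shape, spacing and metadata types", {
  expect_error(ri_tomogram(matrix(1, 2, 2), c(1, 1, 1)), "3D")
  expect_error(ri_tomogram(array(1, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(ri_tomogram(array(1, c(2, 2, 2)), c(1, 1)), "dz, dy, dx")
  t1 <- ri_tomogram(array(1.4, c(2, 3, 4)), c(0.36, 0.115, 0.115),
                    list(wavelength_nm = 532))
  expect_identical(dim(t1), c(2L, 3L, 4L))
  expect_identical(t1$metadata$wavelength_nm, "532")
})

test_that("validation reports findings instead of raising", {
  clean <- constant_tomogram(1.4)
  expect_identical(nrow(validate_tomogram(clean)), 0L)

  v <- clean$values
  v[2, 3, 4] <- NaN
  f <- validate_tomogram(ri_tomogram(v, clean$spacing))
  expect_identical(nrow(f), 1L)
  expect_identical(f$severity, "error")
  expect_match(f$message, "NaN count 1")

  v <- clean$values
  v[sample(length(v), 5)] <- 2.5
  f <- validate_tomogram(ri_tomogram(v, clean$spacing))
  expect_identical(f$severity, "warning")
  expect_identical(f$count, 5L)
  expect_match(f$message, "5 voxels")

  thin <- ri_tomogram(array(1.4, c(1, 4, 4)), c(1, 1, 1))
  expect_true(any(grepl("at least 2 voxels", validate_tomogram(thin)$message)))
})

test_that("TIFF and HDF5 roundtrips preserve values, spacing and metadata", {
  td <- withr::local_tempdir()
  # deterministic formula grid: value(i,j,k) = 1.33 + 0.12 * (i+j+k) / 45
  idx <- 0:15
  v <- array(1.33 + 0.12 * outer(outer(idx, idx, "+"), idx, "+") / 45,
             c(16, 16, 16))
  tomo <- ri_tomogram(v, c(0.36, 0.115, 0.115),
                      list(wavelength_nm = "532", medium_ri = "1.3337"))

  f_tif <- file.path(td, "grid.tiff")
  f_h5 <- file.path(td, "grid.h5")
  write_tomogram(tomo, f_tif)
  write_tomogram(tomo, f_h5)
  r_tif <- read_tomogram(f_tif)
  r_h5 <- read_tomogram(f_h5)

  # float32 storage: exact against the float32-quantized generating formula
  expect_lt(max(abs(r_tif$values - v)), 2^-23 * 1.45)
  expect_identical(r_tif$spacing, tomo$spacing)
  expect_identical(r_tif$metadata$wavelength_nm, "532")

  # HDF5 float64 roundtrip is bit-exact
  expect_identical(r_h5$values, v)
  expect_identical(r_h5$spacing, tomo$spacing)
  expect_identical(r_h5$metadata$medium_ri, "1.3337")

  # format equivalence at float32 precision
  expect_lt(max(abs(r_tif$values - r_h5$values)), 2^-23 * 1.45)

  # float32 HDF5 matches float32 TIFF bit-for-bit
  f_h5f <- file.path(td, "grid32.h5")
  write_tomogram(tomo, f_h5f, dtype = "float")
  expect_identical(read_tomogram(f_h5f)$values, r_tif$values)
})

test_that("second write/read cycle of a TIFF is bit-stable", {
  td <- withr::local_tempdir()
  v <- array(runif(4^3, 1.33, 1.45), c(4, 4, 4))
  t0 <- ri_tomogram(v, c(0.2, 0.1, 0.1))
  write_tomogram(t0, file.path(td, "a.tif"))
  r1 <- read_tomogram(file.path(td, "a.tif"))
  write_tomogram(r1, file.path(td, "b.tif"))
  r2 <- read_tomogram(file.path(td, "b.tif"))
  expect_identical(r1$values, r2$values)
})

test_that("spacing resolution order: override > file metadata > error", {
  td <- withr::local_tempdir()
  v <- array(1.4, c(4, 4, 4))
  # bare HDF5 dataset without attributes
  bare <- file.path(td, "bare.h5")
  rhdf5::h5createFile(bare)
  rhdf5::h5write(v, bare, "raw")
  rhdf5::h5closeAll()
  expect_error(read_tomogram(bare, dataset = "raw"), "spacing")
  r <- read_tomogram(bare, dataset = "raw", spacing = c(0.36, 0.11, 0.11))
  expect_identical(unname(r$spacing), c(0.36, 0.11, 0.11))

  # override beats file metadata
  with_meta <- file.path(td, "meta.h5")
  write_tomogram(ri_tomogram(v, c(0.2, 0.2, 0.2)), with_meta)
  r2 <- read_tomogram(with_meta, spacing = c(0.5, 0.5, 0.5))
  expect_identical(unname(r2$spacing), c(0.5, 0.5, 0.5))
})

test_that("read errors are informative", {
  td <- withr::local_tempdir()
  expect_error(read_tomogram(file.path(td, "nope.tiff")), "not found")
  file.create(file.path(td, "x.xyz"))
  expect_error(read_tomogram(file.path(td, "x.xyz")), "format")
  f <- file.path(td, "d2.h5")
  rhdf5::h5createFile(f)
  rhdf5::h5write(matrix(1, 3, 3), f, "flat")
  rhdf5::h5closeAll()
  expect_error(read_tomogram(f, dataset = "flat", spacing = c(1, 1, 1)),
               "3D")
  expect_error(read_tomogram(f, dataset = "missing"), "missing")
})

test_that("label maps roundtrip with legend and spacing", {
  td <- withr::local_tempdir()
  labels <- array(0L, c(6, 6, 6))
  labels[2:4, 2:4, 2:4] <- 1L
  labels[5, 5, 5] <- 2L
  f <- file.path(td, "labels.h5")
  write_labelmap(labels, c("1" = "bead", "2" = "debris"), f,
                 spacing = c(0.1, 0.1, 0.1))
  lm <- read_labelmap(f)
  expect_identical(lm$labels, labels)
  expect_identical(lm$legend[["2"]], "debris")
  expect_identical(lm$spacing, c(0.1, 0.1, 0.1))
  expect_error(write_labelmap(labels, c("1" = "bead"), f, c(0.1, 0.1, 0.1)),
               "legend")
})

test_that("masks export as 8-bit TIFF", {
  td <- withr::local_tempdir()
  mask <- digitized_ball(3, 12)
  f <- file.path(td, "mask.tif")
  write_mask_tiff(mask, f)
  pages <- tiff::readTIFF(f, all = TRUE)
  back <- array(FALSE, dim(mask))
  for (z in seq_along(pages)) back[z, , ] <- pages[[z]] > 0.5
  expect_identical(back, mask)
})
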