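test_that("noiseless bead phantom is exact and geometrically consistent", {
  ph <- make_bead_phantom(radius_um = 3, shape = c(72, 72, 72),
                          spacing = c(0.1, 0.1, 0.1), noise_sigma = 0)
  expect_true(all(ph$tomogram$values[ph$labels == 1L] == 1.5983))
  expect_true(all(ph$tomogram$values[ph$labels == 0L] == 1.3337))
  # labeled voxel count within 1% of the analytic sphere volume in voxels
  expect_lt(abs(sum(ph$labels == 1L) / ((4 / 3) * pi * 30^3) - 1), 0.01)
})

test_that("contrast-free bead still carries its geometric label map", {
  ph <- make_bead_phantom(radius_um = 1, bead_ri = 1.3337,
                          medium_ri = 1.3337, shape = c(26, 26, 26),
                          spacing = c(0.1, 0.1, 0.1))
  expect_identical(length(unique(as.vector(ph$tomogram$values))), 1L)
  expect_gt(sum(ph$labels == 1L), 0)
})

test_that("bead preconditions are enforced", {
  expect_error(make_bead_phantom(radius_um = 5, shape = c(40, 40, 40),
                                 spacing = c(0.1, 0.1, 0.1)), "margin")
  expect_error(make_bead_phantom(noise_sigma = -1), ">= 0")
})

test_that("diatom phantom ground truth matches the configured bands", {
  ph <- make_diatom_phantom(small_diatom_spec(), seed = 7)
  v <- ph$tomogram$values
  bands <- ph$spec$bands
  expect_true(all(v[ph$labels == 1L] >= bands$frustule[1] &
                  v[ph$labels == 1L] <= bands$frustule[2]))
  expect_true(all(v[ph$labels == 2L] >= bands$protoplasm[1] &
                  v[ph$labels == 2L] <= bands$protoplasm[2]))
  expect_true(all(v[ph$labels == 3L] >= bands$vacuole_membrane[1] &
                  v[ph$labels == 3L] <= bands$vacuole_membrane[2]))
  expect_true(all(v[ph$labels == 4L] >= bands$vacuole_lumen[1] &
                  v[ph$labels == 4L] <= bands$vacuole_lumen[2]))
  expect_true(all(v[ph$labels == 5L] >= bands$chloroplast[1] &
                  v[ph$labels == 5L] <= bands$chloroplast[2]))
  expect_true(all(v[ph$labels == 0L] == ph$spec$medium_ri))
  # all five compartments render
  expect_identical(sort(unique(as.integer(ph$labels))), 0:5)
})

test_that("vacuole enclosed ground truth exceeds membrane-only ground truth", {
  ph <- make_diatom_phantom(small_diatom_spec(), seed = 7)
  expect_gt(sum(ph$labels %in% c(3L, 4L)), sum(ph$labels == 3L))
  expect_gt(sum(ph$labels == 4L), 0)
})

test_that("omitting the vacuole removes labels 3 and 4", {
  spec <- small_diatom_spec()
  spec$vacuole <- NULL
  ph <- make_diatom_phantom(spec, seed = 7)
  expect_false(any(ph$labels %in% c(3L, 4L)))
})

test_that("phantom generation is bit-reproducible under a seed", {
  a <- make_diatom_phantom(small_diatom_spec(), seed = 3)
  b <- make_diatom_phantom(small_diatom_spec(), seed = 3)
  c2 <- make_diatom_phantom(small_diatom_spec(), seed = 4)
  expect_identical(a$tomogram$values, b$tomogram$values)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$tomogram$values, c2$tomogram$values))
})

test_that("phantom spec roundtrips through YAML and JSON", {
  td <- withr::local_tempdir()
  spec <- small_diatom_spec()
  for (ext in c("yaml", "json")) {
    f <- file.path(td, paste0("spec.", ext))
    write_phantom_spec(spec, f)
    back <- read_phantom_spec(f)
    expect_identical(make_diatom_phantom(back, seed = 5)$tomogram$values,
                     make_diatom_phantom(spec, seed = 5)$tomogram$values)
  }
})

test_that("blurring a constant field is the identity", {
  tomo <- constant_tomogram(1.3337, c(24, 24, 24))
  out <- apply_optical_blur(tomo)
  expect_lt(max(abs(out$values - 1.3337)), 1e-12)
})

test_that("blur has the requested per-axis FWHM and conserves RI excess", {
  n <- 41
  sp <- c(0.05, 0.05, 0.05)
  v <- array(1.3337, c(n, n, n))
  v[21, 21, 21] <- 1.6
  tomo <- ri_tomogram(v, sp, list(medium_ri = "1.3337"))
  out <- apply_optical_blur(tomo, lateral_fwhm = 0.110, axial_fwhm = 0.360)

  fwhm_of <- function(profile, d) {
    e <- profile - 1.3337
    half <- max(e) / 2
    above <- which(e >= half)
    lo <- min(above); hi <- max(above)
    # linear interpolation of the half-max crossings
    f_lo <- lo - (e[lo] - half) / (e[lo] - e[lo - 1])
    f_hi <- hi + (e[hi] - half) / (e[hi] - e[hi + 1])
    (f_hi - f_lo) * d
  }
  expect_lt(abs(fwhm_of(out$values[, 21, 21], sp[1]) / 0.360 - 1), 0.10)
  expect_lt(abs(fwhm_of(out$values[21, , 21], sp[2]) / 0.110 - 1), 0.10)
  expect_lt(abs(fwhm_of(out$values[21, 21, ], sp[3]) / 0.110 - 1), 0.10)
  # total excess above medium conserved to 0.1% for an interior impulse
  expect_lt(abs(sum(out$values - 1.3337) / sum(v - 1.3337) - 1), 0.001)
})

test_that("blur below a tenth of a voxel is skipped with a warning", {
  tomo <- constant_tomogram(1.4, c(8, 8, 8), spacing = c(10, 10, 10))
  expect_warning(apply_optical_blur(tomo), "skipped")
})

test_that("blurred bead keeps its interior RI", {
  ph <- make_bead_phantom()
  blurred <- apply_optical_blur(ph$tomogram)
  interior <- erode_mask(array(ph$labels == 1L, dim(ph$labels)), 2L)
  expect_lt(abs(mean_ri(blurred, interior) - 1.5983), 0.002)
})

test_that("additive noise is seeded, reproducible and correctly scaled", {
  tomo <- constant_tomogram(1.4, c(50, 50, 50))
  expect_identical(add_noise(tomo, 0)$values, tomo$values)
  a <- add_noise(tomo, 0.001, seed = 9)
  b <- add_noise(tomo, 0.001, seed = 9)
  expect_identical(a$values, b$values)
  expect_lt(abs(stats::sd(a$values - tomo$values) / 0.001 - 1), 0.05)
  expect_error(add_noise(tomo, -0.001), ">= 0")
})
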