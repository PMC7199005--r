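test_that("mask volume has the closed form count x voxel volume", {
  expect_identical(mask_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
  block <- array(TRUE, c(10, 10, 10))
  expect_equal(mask_volume(block, c(0.5, 0.5, 0.5)), 125)
  ball <- digitized_ball(20)
  expect_lt(abs(mask_volume(ball, c(1, 1, 1)) / ((4 / 3) * pi * 20^3) - 1),
            0.01)
})

test_that("surface area recovers analytic solids", {
  ball <- digitized_ball(20)
  expect_lt(abs(surface_area(ball, c(1, 1, 1)) / (4 * pi * 400) - 1), 0.03)

  box <- digitized_box(c(20, 10, 10))
  expect_lt(abs(surface_area(box, c(1, 1, 1)) / 1000 - 1), 0.05)

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  a1 <- surface_area(single, c(1, 1, 1))
  expect_gt(a1, 0)
  expect_lt(a1, 6)   # below the voxel-face hull of a unit cube

  expect_error(surface_area(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("projected area counts silhouette pixels in physical units", {
  ball <- digitized_ball(20)
  for (ax in c("z", "y", "x")) {
    expect_lt(abs(projected_area(ball, c(1, 1, 1), ax) / (pi * 400) - 1),
              0.02)
  }
  # 1-voxel-thick sheet: n pixels x dy*dx, independent of dz
  sheet <- array(FALSE, c(6, 5, 7)); sheet[3, , ] <- TRUE
  expect_equal(projected_area(sheet, c(99, 0.2, 0.1), "z"), 35 * 0.02)
  expect_identical(projected_area(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)
})

test_that("mean RI averages tomogram values over the mask", {
  tomo <- constant_tomogram(1.40, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[1:2, 1, 1] <- TRUE
  expect_identical(mean_ri(tomo, m), 1.40)
  v <- tomo$values; v[1, 1, 1] <- 1.30; v[2, 1, 1] <- 1.50
  expect_equal(mean_ri(ri_tomogram(v, tomo$spacing), m), 1.40)
  expect_error(mean_ri(tomo, array(FALSE, c(4, 4, 4))), "empty")
  expect_error(mean_ri(tomo, array(TRUE, c(3, 3, 3))), "dimensions")
})

test_that("Wadell sphericity matches closed forms and the printed panel", {
  r <- c(0.7, 3, 12)
  expect_equal(sphericity((4 / 3) * pi * r^3, 4 * pi * r^2), rep(1, 3))
  expect_lt(abs(sphericity(147.4674, 288.5568) - 0.4678), 0.001)
  expect_lt(abs(sphericity(42.5344, 114.9186) - 0.5128), 0.001)
  expect_error(sphericity(-1, 5), "positive")
})

test_that("ball sphericity approaches 1 with radius", {
  psi <- vapply(c(10, 15, 20), function(r) {
    b <- digitized_ball(r)
    sphericity(mask_volume(b, c(1, 1, 1)), surface_area(b, c(1, 1, 1)))
  }, numeric(1))
  expect_true(all(diff(psi) > -0.002))        # non-decreasing up to jitter
  expect_true(all(abs(psi[2:3] - 1) < 0.03))  # within 3% from radius 15
})

test_that("spacing rescaling transforms volume, areas and leaves ratios", {
  ball <- digitized_ball(10)
  s <- 2.5
  v1 <- mask_volume(ball, c(1, 1, 1)); v2 <- mask_volume(ball, rep(s, 3))
  a1 <- surface_area(ball, c(1, 1, 1)); a2 <- surface_area(ball, rep(s, 3))
  p1 <- projected_area(ball, c(1, 1, 1)); p2 <- projected_area(ball, rep(s, 3))
  expect_equal(v2 / v1, s^3)
  expect_equal(a2 / a1, s^2, tolerance = 1e-10)
  expect_equal(p2 / p1, s^2)
  expect_equal(sphericity(v1, a1), sphericity(v2, a2), tolerance = 1e-10)
})

test_that("projection of a convex solid is at most half its surface area", {
  for (mask in list(digitized_ball(12), digitized_box(c(14, 8, 6)))) {
    a <- surface_area(mask, c(1, 1, 1))
    for (ax in c("z", "y", "x")) {
      expect_lte(projected_area(mask, c(1, 1, 1), ax), a / 2 * 1.02)
    }
  }
})

test_that("full panel on a constant-RI ball phantom is self-consistent", {
  # ball of RI 1.40 in medium, radius 2 um at 0.1 um voxels (odd grid, so
  # the digitized ball is centred on a voxel)
  ph <- make_bead_phantom(radius_um = 2, bead_ri = 1.40,
                          shape = c(53, 53, 53), spacing = c(0.1, 0.1, 0.1))
  cm <- segment_compartment(ph$tomogram, ri_band("ball", 1.39, 1.41))
  st <- compute_stats(ph$tomogram, cm)
  expect_lt(abs(st$sphericity - 1), 0.02)
  expect_lt(abs(st$mean_ri - 1.40), 0.001)
  expect_identical(st$volume_um3, st$volume_color_um3)
  expect_identical(st$threshold_ri, st$ri_min)
  # dry mass equals concentration x volume by construction; cross-check the
  # voxel-wise integral explicitly
  expect_equal(st$dry_mass_pg,
               compartment_dry_mass(ph$tomogram, cm$enclosed_mask),
               tolerance = 1e-10)
})

test_that("mesh export writes valid PLY and STL", {
  td <- withr::local_tempdir()
  mesh <- mask_mesh(digitized_ball(4, 14), c(0.1, 0.1, 0.1))
  ply <- file.path(td, "m.ply"); stl <- file.path(td, "m.stl")
  write_mesh(mesh, ply); write_mesh(mesh, stl)
  head <- readLines(ply, n = 4)
  expect_identical(head[1], "ply")
  expect_match(head[3], sprintf("element vertex %d", nrow(mesh$vertices)))
  stl_txt <- readLines(stl)
  expect_identical(sum(grepl("facet normal", stl_txt)), nrow(mesh$faces))
})
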