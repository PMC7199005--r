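test_that("band membership uses closed-interval semantics", {
  vals <- c(1.352, 1.357, 1.3519, 1.3571, 1.3545, 1.3337, 1.40, 1.355)
  tomo <- ri_tomogram(array(vals, c(2, 2, 2)), c(1, 1, 1))
  m <- band_mask(tomo, ri_band("frustule", 1.352, 1.357))
  expect_identical(as.vector(m),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))

  all_in <- constant_tomogram(1.3545)
  expect_true(all(band_mask(all_in, ri_band("b", 1.352, 1.357))))
  all_out <- constant_tomogram(1.3337)
  expect_false(any(band_mask(all_out, ri_band("b", 1.352, 1.357))))
})

test_that("largest component selection keeps the bigger object", {
  m <- array(FALSE, c(24, 24, 24))
  m[4:9, 4:9, 4:9] <- TRUE                                        # 216 voxels
  m[18:19, 18:19, 18:19] <- TRUE                                  # 8 voxels
  out <- largest_component(m)
  expect_true(all(out[4:9, 4:9, 4:9]))
  expect_false(any(out[18:19, 18:19, 18:19]))

  single <- digitized_ball(4, 14)
  expect_identical(largest_component(single), single)
  expect_error(largest_component(array(FALSE, c(3, 3, 3))), "foreground")
})

test_that("equal-size components tie-break to the earliest voxel", {
  m <- array(FALSE, c(16, 16, 16))
  m[2:3, 2:3, 2:3] <- TRUE
  m[10:11, 10:11, 10:11] <- TRUE
  out <- largest_component(m)
  expect_true(out[2, 2, 2])
  expect_false(out[10, 10, 10])
})

test_that("closing is identity at radius 0, idempotent, and seals punctures", {
  shell <- hollow_shell(6)
  expect_identical(close_mask(shell, 0L), shell)

  cube <- digitized_box(c(8, 8, 8))
  once <- close_mask(cube, 2L)
  expect_identical(close_mask(once, 2L), once)   # idempotence
  expect_true(all(cube[cube] == once[cube]))     # interior unchanged

  # puncture one pole voxel of a closed shell: filling leaks until closed
  pierced <- shell
  c0 <- (dim(shell) + 1) %/% 2
  pole <- which(shell[, c0[2], c0[3]])[1]
  pierced[pole, c0[2], c0[3]] <- FALSE
  leaked <- fill_enclosed(pierced)
  sealed <- fill_enclosed(close_mask(pierced, 1L))
  full <- fill_enclosed(shell)
  expect_lt(sum(leaked), 0.5 * sum(full))
  expect_gte(sum(sealed), sum(full) - 8)
})

test_that("filling recovers cavities but not border-open ones", {
  ball <- digitized_ball(6)
  expect_identical(fill_enclosed(ball), ball)   # solid: identity

  shell <- hollow_shell(8)
  filled <- fill_enclosed(shell)
  expect_lt(abs(sum(filled) / sum(digitized_ball(8)) - 1), 0.02)

  # open box flush with the grid border: cavity connects to the outside
  d <- c(10, 10, 10)
  open_box <- array(FALSE, d)
  open_box[2:9, 2:9, 2:9] <- TRUE
  open_box[3:8, 3:8, 3:8] <- FALSE    # hollow
  open_box[1:2, 3:8, 3:8] <- FALSE    # face removed, opening to border
  expect_identical(fill_enclosed(open_box), open_box)
})

test_that("filling is idempotent and monotone on nested shells", {
  shell <- hollow_shell(7)
  f1 <- fill_enclosed(shell)
  expect_identical(fill_enclosed(f1), f1)
  bigger <- dilate_mask(shell, 1L)
  expect_true(all(fill_enclosed(bigger)[f1]))   # A <= B => fill(A) <= fill(B)
})

test_that("filling agrees with the brute-force border-reachability oracle", {
  withr::with_seed(42, {
    for (case in 1:30) {
      d <- sample(6:14, 3, replace = TRUE)
      m <- array(runif(prod(d)) < runif(1, 0.2, 0.6), d)
      expect_identical(fill_enclosed(m), oracle_fill(m))
    }
  })
})

test_that("compartment segmentation separates colour from enclosed volume", {
  ph <- make_diatom_phantom(small_diatom_spec(), seed = 7)
  tomo <- ph$tomogram

  chl <- segment_compartment(tomo, ri_band("chloroplast", 1.403, 1.436))
  expect_identical(sum(chl$band_mask), sum(chl$enclosed_mask))

  vac <- segment_compartment(tomo, ri_band("vacuole", 1.388, 1.395))
  expect_gt(sum(vac$enclosed_mask), sum(vac$band_mask))

  # band_mask subset of enclosed_mask; difference touches no border
  expect_true(all(vac$enclosed_mask[vac$band_mask]))
  diffm <- vac$enclosed_mask & !vac$band_mask
  d <- dim(diffm)
  expect_false(any(diffm[1, , ]) || any(diffm[d[1], , ]) ||
               any(diffm[, 1, ]) || any(diffm[, d[2], ]) ||
               any(diffm[, , 1]) || any(diffm[, , d[3]]))

  expect_error(
    segment_compartment(constant_tomogram(), ri_band("b", 1.4, 1.5)),
    "band matched no voxels")
})

test_that("noiseless phantom segmentation recovers ground-truth volumes", {
  ph <- make_diatom_phantom(small_diatom_spec(), seed = 7)
  tomo <- ph$tomogram
  gt <- function(ids) sum(ph$labels %in% ids)

  frustule <- segment_compartment(tomo, ri_band("frustule", 1.352, 1.357))
  expect_lt(abs(sum(frustule$enclosed_mask) / gt(1:5) - 1), 0.05)

  vac <- segment_compartment(tomo, ri_band("vacuole", 1.388, 1.395))
  expect_lt(abs(sum(vac$enclosed_mask) / gt(c(3, 4)) - 1), 0.05)

  chl <- segment_compartment(tomo, ri_band("chloroplast", 1.403, 1.436))
  expect_lt(abs(sum(chl$enclosed_mask) / gt(5) - 1), 0.05)
})
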