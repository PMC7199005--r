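# Fixtures are generated in code: digitized analytic solids, a reduced
# diatom phantom for fast tests, and a brute-force cavity-filling oracle.

digitized_ball <- function(r, n = 2 * r + 9, spacing = c(1, 1, 1)) {
  stopifnot(length(n) %in% c(1, 3))
  if (length(n) == 1) n <- rep(n, 3)
  e1 <- (((1:n[1]) - (n[1] + 1) / 2) * spacing[1])^2
  e2 <- (((1:n[2]) - (n[2] + 1) / 2) * spacing[2])^2
  e3 <- (((1:n[3]) - (n[3] + 1) / 2) * spacing[3])^2
  array(outer(outer(e1, e2, "+"), e3, "+") <= r^2, n)
}

digitized_box <- function(dim_box, n = dim_box + 10) {
  m <- array(FALSE, n)
  lo <- (n - dim_box) %/% 2 + 1
  m[lo[1]:(lo[1] + dim_box[1] - 1),
    lo[2]:(lo[2] + dim_box[2] - 1),
    lo[3]:(lo[3] + dim_box[3] - 1)] <- TRUE
  m
}

# hollow spherical shell: outer radius r_o, 1-voxel wall via erosion
hollow_shell <- function(r_o, n = 2 * r_o + 9) {
  b <- digitized_ball(r_o, n)
  b & !erode_mask(b, 1L)
}

# reduced diatom phantom spec: same structure as the default, desk-second
# sized (~740k voxels)
small_diatom_spec <- function() {
  diatom_phantom_spec(
    shape = c(48L, 96L, 160L),
    spacing = c(0.36, 0.23, 0.23),
    cell_length_um = 16,
    cell_radius_um = 2.0,
    vacuole = list(offset_um = 2.5, semi_um = c(0.9, 1.1, 2.2)),
    chloroplasts = list(
      list(offset_um = c(0, 0, -2.2), semi_um = c(0.6, 0.8, 2.6))
    )
  )
}

# independent cavity-filling oracle: iterative 6-neighbour growth of the
# border-connected background, written against array shifts rather than the
# package's graph traversal
oracle_fill <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  reach <- array(FALSE, d)
  reach[1, , ] <- bg[1, , ];  reach[d[1], , ] <- bg[d[1], , ]
  reach[, 1, ] <- reach[, 1, ] | bg[, 1, ]
  reach[, d[2], ] <- reach[, d[2], ] | bg[, d[2], ]
  reach[, , 1] <- reach[, , 1] | bg[, , 1]
  reach[, , d[3]] <- reach[, , d[3]] | bg[, , d[3]]
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | !reach
}

constant_tomogram <- function(value = 1.3337, n = c(8, 8, 8),
                              spacing = c(0.1, 0.1, 0.1)) {
  ri_tomogram(array(value, n), spacing)
}
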