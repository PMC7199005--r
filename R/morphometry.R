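#' Mask volume in physical units
#'
#' Voxel count times voxel volume `dz * dy * dx`.
#'
#' @param mask 3D logical array.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @return Volume in um^3.
#' @export
mask_volume <- function(mask, spacing) {
  check_mask(mask)
  stopifnot(is.numeric(spacing), length(spacing) == 3L, all(spacing > 0))
  sum(mask) * prod(spacing)
}

#' Isosurface area of a mask
#'
#' Area of the triangulated isosurface from [mask_mesh()], in um^2. The
#' default Taubin smoothing removes the voxelization staircase; see
#' [mask_mesh()] for the estimator's measured accuracy.
#'
#' @inheritParams mask_mesh
#' @return Surface area in um^2.
#' @export
surface_area <- function(mask, spacing, smooth_iterations = 100L,
                         lambda = 0.5, mu = -0.53, clamp_voxels = 0.45) {
  if (!any(mask)) abort("empty mask")
  mesh_area(mask_mesh(mask, spacing, smooth_iterations, lambda, mu,
                      clamp_voxels))
}

#' Projected (silhouette) area of a mask
#'
#' Number of 2D pixels covered by at least one foreground voxel along the
#' projection axis, times the in-plane pixel area. The default projection is
#' along the optical (z) axis.
#'
#' @param mask 3D logical array.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @param axis `"z"` (default), `"y"` or `"x"`.
#' @return Projected area in um^2.
#' @export
projected_area <- function(mask, spacing, axis = c("z", "y", "x")) {
  check_mask(mask)
  axis <- match.arg(axis)
  ax <- match(axis, c("z", "y", "x"))
  keep <- setdiff(1:3, ax)
  sil <- apply(mask, keep, any)
  sum(sil) * prod(spacing[keep])
}

#' Mean refractive index over a mask
#'
#' Arithmetic mean of tomogram values over the mask's voxels. In the
#' morphometric panel this is computed over the *enclosed* region: for a
#' membrane-bounded compartment the interior voxels are included, which is
#' why a compartment's mean RI can lie outside its own band.
#'
#' @param tomo An [ri_tomogram()].
#' @param mask 3D logical array, nonempty, same shape as the tomogram.
#' @return Mean RI, dimensionless.
#' @export
mean_ri <- function(tomo, mask) {
  stopifnot(is_ri_tomogram(tomo))
  check_mask(mask)
  if (!identical(dim(mask), dim(tomo$values))) {
    abort("mask and tomogram dimensions differ")
  }
  if (!any(mask)) abort("empty mask")
  mean(tomo$values[mask])
}

#' Wadell sphericity
#'
#' `psi = pi^(1/3) * (6 V)^(2/3) / A`: the surface area of the sphere with
#' the object's volume divided by the object's actual surface area. Exactly 1
#' for a sphere, below 1 for every other shape.
#'
#' @param volume Volume in um^3, `> 0`.
#' @param area Surface area in um^2, `> 0`.
#' @return Sphericity, dimensionless in (0, 1\] (up to discretization error).
#' @examples
#' sphericity(147.4674, 288.5568)  # 0.4678
#' @export
sphericity <- function(volume, area) {
  if (any(volume <= 0) || any(area <= 0)) {
    abort("`volume` and `area` must be positive")
  }
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

#' Full morphometric panel for one segmented compartment
#'
#' Assembles the ten per-compartment statistics of the morphometric panel
#' from a [segment_compartment()] result:
#' volume (enclosed), volume of colour (in-band), surface area and projected
#' area of the enclosed region, mean RI over the enclosed region, dry-mass
#' concentration from the mean RI via the Barer relation, dry mass
#' (= concentration x volume, identical to the voxel-wise integral by
#' linearity), dry mass of colour (voxel-wise integral over in-band voxels),
#' Wadell sphericity, and the band's threshold RI (= its lower bound).
#'
#' @param tomo An [ri_tomogram()].
#' @param masks A `compartment_masks` object.
#' @param medium A [medium_model()].
#' @param projection_axis Axis for [projected_area()].
#' @param smooth_iterations Taubin iterations for [surface_area()].
#' @return One-row tibble with columns `label`, `ri_min`, `ri_max`,
#'   `volume_um3`, `volume_color_um3`, `surface_area_um2`,
#'   `projected_area_um2`, `mean_ri`, `concentration_pg_per_um3`,
#'   `dry_mass_pg`, `dry_mass_color_pg`, `sphericity`, `threshold_ri`.
#' @examples
#' ph <- make_bead_phantom(radius_um = 1, shape = c(24, 24, 24),
#'                         spacing = c(0.1, 0.1, 0.1))
#' cm <- segment_compartment(ph$tomogram, ri_band("bead", 1.58, 1.62))
#' compute_stats(ph$tomogram, cm)
#' @export
compute_stats <- function(tomo, masks, medium = medium_model(),
                          projection_axis = "z", smooth_iterations = 100L) {
  stopifnot(is_ri_tomogram(tomo), inherits(masks, "compartment_masks"))
  sp <- tomo$spacing
  vol <- mask_volume(masks$enclosed_mask, sp)
  vol_color <- mask_volume(masks$band_mask, sp)
  area <- surface_area(masks$enclosed_mask, sp, smooth_iterations)
  proj <- projected_area(masks$enclosed_mask, sp, projection_axis)
  mri <- mean_ri(tomo, masks$enclosed_mask)
  conc <- concentration_from_ri(mri, medium)
  dm <- conc * vol
  dm_voxelwise <- compartment_dry_mass(tomo, masks$enclosed_mask, medium)
  stopifnot(isTRUE(all.equal(dm, dm_voxelwise, tolerance = 1e-8)))
  dm_color <- band_dry_mass(tomo, masks$band_mask, medium)
  psi <- sphericity(vol, area)
  stopifnot(vol_color <= vol, psi > 0)
  if (psi > 1 + 0.02) {
    # voxel-scale compartments (noise specks, debris fragments) sit below the
    # area estimator's resolution and can report psi > 1; keep the value but
    # flag it rather than abort a multi-band run
    warn(sprintf(
      "sphericity %.3f > 1 for '%s': compartment spans only %d voxels, below the surface-area estimator's resolution",
      psi, masks$band$label, sum(masks$enclosed_mask)))
  }
  tibble(
    label = masks$band$label,
    ri_min = masks$band$ri_min,
    ri_max = masks$band$ri_max,
    volume_um3 = vol,
    volume_color_um3 = vol_color,
    surface_area_um2 = area,
    projected_area_um2 = proj,
    mean_ri = mri,
    concentration_pg_per_um3 = conc,
    dry_mass_pg = dm,
    dry_mass_color_pg = dm_color,
    sphericity = psi,
    threshold_ri = masks$band$ri_min
  )
}
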