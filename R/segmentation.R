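#' In-band voxel mask
#'
#' Marks every voxel whose RI lies inside the closed interval
#' `[ri_min, ri_max]` of the band (both endpoints inclusive).
#'
#' @param tomo An [ri_tomogram()].
#' @param band A single band (one-row tibble from [ri_band()], or a list with
#'   `ri_min`/`ri_max`).
#' @return 3D logical array with the tomogram's dimensions.
#' @export
band_mask <- function(tomo, band) {
  stopifnot(is_ri_tomogram(tomo))
  band <- as_band_row(band)
  m <- tomo$values >= band$ri_min & tomo$values <= band$ri_max
  m[is.na(m)] <- FALSE
  m
}

#' Keep the largest connected component of a mask
#'
#' Used to isolate the cell from co-occurring debris in the field of view
#' (seawater samples carry fibre-like objects and other particles). Ties in
#' component size are broken deterministically in favour of the component
#' containing the smallest linear voxel index (array order z fastest, then
#' y, then x).
#'
#' @param mask 3D logical array, at least one `TRUE` voxel.
#' @param connectivity Foreground connectivity: 6, 18 or 26 (default).
#' @return 3D logical array retaining only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  check_mask(mask)
  if (!any(mask)) abort("no foreground voxels in mask")
  connectivity <- match_connectivity(connectivity)
  lab <- .cc_label(mask, dim(mask), connectivity)
  sizes <- tabulate(lab, attr(lab, "n_components"))
  # components are numbered in discovery (raster) order, so which.max's
  # first-maximum rule realises the smallest-minimum-index tie-break
  keep <- which.max(sizes)
  out <- array(lab == keep, dim(mask))
  out
}

#' Morphological closing with a digital ball
#'
#' Dilation followed by erosion with a Chebyshev-ball structuring element
#' (a cube of side `2*radius + 1` voxels, the dual of the 26-connected
#' foreground used elsewhere). Seals sub-voxel gaps in thin shells — the frustule and
#' vacuole-membrane bands sit near the optical resolution limit, where noise
#' can puncture a one-voxel wall and make hole filling leak. Radius 0 is the
#' identity.
#'
#' @param mask 3D logical array.
#' @param radius_voxels Integer ball radius in voxels, `>= 0`.
#' @return Closed 3D logical array.
#' @export
close_mask <- function(mask, radius_voxels = 1L) {
  check_mask(mask)
  radius_voxels <- as.integer(radius_voxels)
  if (radius_voxels < 0L) abort("`radius_voxels` must be >= 0")
  if (radius_voxels == 0L) return(mask)
  d <- dim(mask)
  out <- .ball_morph(mask, d, radius_voxels, TRUE, TRUE)
  out <- .ball_morph(out, d, radius_voxels, FALSE, TRUE)
  array(out, d)
}

#' Fill enclosed cavities of a mask
#'
#' Background is flood-filled from every grid-border voxel with
#' 6-connectivity; background voxels the flood never reaches are interior
#' cavities and become foreground. Foreground objects use 26-connectivity
#' elsewhere in the package; the 6/26 pairing is the standard complementary
#' choice that prevents topological leaks through voxel corners. A cavity
#' open to the border (e.g. a shell with a missing face at the grid edge)
#' is not filled.
#'
#' @param mask 3D logical array.
#' @return 3D logical array: `mask` plus its enclosed cavities.
#' @export
fill_enclosed <- function(mask) {
  check_mask(mask)
  d <- dim(mask)
  outside <- .reach_border(mask, d)
  array(mask | !outside, d)
}

#' Segment one compartment from an RI band
#'
#' Composite segmentation used for each compartment: in-band thresholding,
#' morphological closing, optional largest-component selection, then cavity
#' filling. Two masks are returned, mirroring the two volume statistics of
#' the morphometric panel:
#' * `band_mask` — the cleaned in-band ("colour") voxels: the post-cleanup
#'   component intersected with the raw in-band predicate, so closing-added
#'   voxels are never counted as colour volume;
#' * `enclosed_mask` — the filled compartment, including interior cavities
#'   (e.g. the vacuole lumen bounded by its membrane band).
#'
#' `band_mask` is always a subset of `enclosed_mask`, and the difference
#' touches no grid border.
#'
#' @inheritParams band_mask
#' @param closing_radius Ball radius (voxels) for [close_mask()]; 0 reproduces
#'   pure thresholding.
#' @param connectivity Foreground connectivity for component selection.
#' @param keep_largest Keep only the largest connected component (default
#'   `TRUE`; the instrument's field of view may contain debris).
#' @return An object of class `compartment_masks`: list with `band_mask`,
#'   `enclosed_mask`, `band`, `params`.
#' @examples
#' ph <- make_bead_phantom(radius_um = 1, shape = c(24, 24, 24),
#'                         spacing = c(0.1, 0.1, 0.1))
#' cm <- segment_compartment(ph$tomogram, ri_band("bead", 1.58, 1.62))
#' sum(cm$band_mask) == sum(cm$enclosed_mask)  # solid body
#' @export
segment_compartment <- function(tomo, band, closing_radius = 1L,
                                connectivity = 26L, keep_largest = TRUE) {
  stopifnot(is_ri_tomogram(tomo))
  band <- as_band_row(band)
  raw <- band_mask(tomo, band)
  if (!any(raw)) {
    abort(sprintf("band matched no voxels: '%s' [%g, %g]",
                  band$label, band$ri_min, band$ri_max))
  }
  cleaned <- close_mask(raw, closing_radius)
  if (keep_largest) cleaned <- largest_component(cleaned, connectivity)
  enclosed <- fill_enclosed(cleaned)
  structure(
    list(
      band_mask = array(cleaned & raw, dim(raw)),
      enclosed_mask = enclosed,
      band = band,
      params = list(closing_radius = as.integer(closing_radius),
                    connectivity = as.integer(connectivity),
                    keep_largest = keep_largest)
    ),
    class = "compartment_masks"
  )
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat(sprintf(
    "<compartment_masks> '%s' [%.4f, %.4f]: %d in-band voxels, %d enclosed\n",
    x$band$label, x$band$ri_min, x$band$ri_max,
    sum(x$band_mask), sum(x$enclosed_mask)))
  invisible(x)
}

check_mask <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    abort("mask must be a 3D logical array")
  }
  invisible(mask)
}

match_connectivity <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("connectivity must be 6, 18 or 26")
  }
  connectivity
}

#' Erode or dilate a mask with a digital ball
#'
#' Plain morphological erosion/dilation with a Euclidean digital ball
#' (offsets with `dz^2 + dy^2 + dx^2 <= radius^2`). Erosion is used e.g. to strip partial-volume
#' boundary shells before measuring a compartment's interior RI (the bead
#' validation protocol erodes by 2 voxels).
#'
#' @param mask 3D logical array.
#' @param radius_voxels Integer ball radius in voxels, `>= 0`.
#' @return 3D logical array.
#' @export
erode_mask <- function(mask, radius_voxels = 1L) {
  check_mask(mask)
  radius_voxels <- as.integer(radius_voxels)
  if (radius_voxels < 0L) abort("`radius_voxels` must be >= 0")
  if (radius_voxels == 0L) return(mask)
  array(.ball_morph(mask, dim(mask), radius_voxels, FALSE, FALSE), dim(mask))
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, radius_voxels = 1L) {
  check_mask(mask)
  radius_voxels <- as.integer(radius_voxels)
  if (radius_voxels < 0L) abort("`radius_voxels` must be >= 0")
  if (radius_voxels == 0L) return(mask)
  array(.ball_morph(mask, dim(mask), radius_voxels, TRUE, FALSE), dim(mask))
}
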