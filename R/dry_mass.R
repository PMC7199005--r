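#' Medium model for the Barer refractive-increment relation
#'
#' Dry-mass quantification from RI rests on the linear Barer relation
#' `n = n_medium + alpha * C`, where `C` is the dry-mass concentration and
#' `alpha` the specific refractive increment. Defaults: `n_medium = 1.3337`
#' (water at green-laser wavelengths, and the value consistent with the
#' reference morphometric panel, see [check_reference_panel()]) and
#' `alpha = 0.19` um^3/pg — numerically equal to the standard 0.19 mL/g
#' protein increment.
#'
#' @param n_medium Medium refractive index, dimensionless, in \[1.30, 1.40\].
#' @param alpha Specific refractive increment in um^3/pg, `> 0`.
#' @return An object of class `medium_model`.
#' @examples
#' medium_model()
#' @export
medium_model <- function(n_medium = 1.3337, alpha = 0.19) {
  if (!is.numeric(alpha) || alpha <= 0) abort("`alpha` must be positive")
  if (!is.numeric(n_medium) || n_medium < 1.30 || n_medium > 1.40) {
    abort("`n_medium` must lie in [1.30, 1.40]")
  }
  structure(list(n_medium = as.double(n_medium), alpha = as.double(alpha)),
            class = "medium_model")
}

#' @export
print.medium_model <- function(x, ...) {
  cat(sprintf("<medium_model> n_medium = %.4f, alpha = %.3f um^3/pg\n",
              x$n_medium, x$alpha))
  invisible(x)
}

#' Dry-mass concentration from refractive index
#'
#' Inverts the Barer relation: `C = (n - n_medium) / alpha`, in pg/um^3.
#' Values below the medium RI give negative concentrations and are returned
#' as-is; clamping is the caller's decision (see `clamp_negative` in
#' [compartment_dry_mass()]).
#'
#' @param n Refractive index (vectorised).
#' @param medium A [medium_model()].
#' @return Concentration(s) in pg/um^3.
#' @examples
#' concentration_from_ri(1.3989)  # 0.3432 pg/um^3
#' @export
concentration_from_ri <- function(n, medium = medium_model()) {
  stopifnot(inherits(medium, "medium_model"))
  (n - medium$n_medium) / medium$alpha
}

#' Integrated dry mass of a compartment
#'
#' Sums `concentration_from_ri(RI) * voxel volume` over the mask voxels, in
#' picograms. By linearity this equals mean concentration times total volume;
#' both code paths are computed and checked against each other.
#' `compartment_dry_mass()` is meant for the enclosed (filled) mask,
#' `band_dry_mass()` for the in-band "colour" mask — for a solid compartment
#' the two coincide.
#'
#' @param tomo An [ri_tomogram()].
#' @param mask 3D logical array (enclosed or in-band mask).
#' @param medium A [medium_model()].
#' @param clamp_negative Clamp per-voxel concentrations below zero before
#'   integrating (default `FALSE`: the unbiased estimator).
#' @return Dry mass in pg.
#' @export
compartment_dry_mass <- function(tomo, mask, medium = medium_model(),
                                 clamp_negative = FALSE) {
  stopifnot(is_ri_tomogram(tomo))
  check_mask(mask)
  if (!identical(dim(mask), dim(tomo$values))) {
    abort("mask and tomogram dimensions differ")
  }
  if (!any(mask)) abort("empty mask")
  conc <- concentration_from_ri(tomo$values[mask], medium)
  if (clamp_negative) conc <- pmax(conc, 0)
  voxel <- prod(tomo$spacing)
  total <- sum(conc) * voxel
  if (!clamp_negative) {
    via_mean <- mean(conc) * (sum(mask) * voxel)
    stopifnot(isTRUE(all.equal(total, via_mean, tolerance = 1e-10)))
  }
  total
}

#' @rdname compartment_dry_mass
#' @export
band_dry_mass <- function(tomo, mask, medium = medium_model(),
                          clamp_negative = FALSE) {
  compartment_dry_mass(tomo, mask, medium, clamp_negative)
}

#' Mean in-band RI implied by a (dry mass, volume) pair
#'
#' Diagnostic inverse of the Barer relation:
#' `n = n_medium + alpha * (m / V)`. Applied to a panel's printed
#' "dry mass of colour" and "volume of colour", the result should fall inside
#' the compartment's RI band — a self-consistency check on the panel.
#'
#' @param dry_mass_color Dry mass of the in-band voxels, pg.
#' @param volume_color Volume of the in-band voxels, um^3, `> 0`.
#' @param medium A [medium_model()].
#' @return Implied mean RI, dimensionless.
#' @examples
#' implied_band_mean_ri(4.5874, 38.4381)  # ~1.3564, inside [1.352, 1.357]
#' @export
implied_band_mean_ri <- function(dry_mass_color, volume_color,
                                 medium = medium_model()) {
  stopifnot(inherits(medium, "medium_model"))
  if (any(volume_color <= 0)) abort("`volume_color` must be positive")
  medium$n_medium + medium$alpha * dry_mass_color / volume_color
}
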