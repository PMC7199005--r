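#' Reference morphometric panel for a living diatom
#'
#' The published per-compartment morphometric panel measured by
#' holotomography on a living *Cylindrotheca* sp. cell in seawater-derived
#' medium: four compartments identified by RI bands — frustule (black,
#' 1.352–1.357), protoplasm (green, 1.363–1.381), vacuole (blue,
#' 1.388–1.395), chloroplast (red, 1.403–1.436) — with volume, in-band
#' ("colour") volume, surface area, projected area, mean RI, dry-mass
#' concentration, dry mass, in-band dry mass, sphericity, and threshold RI
#' per compartment.
#'
#' The panel's internal arithmetic is reproducible from these printed values
#' alone (see [check_reference_panel()]): the sphericity row follows from
#' volume and surface area, the concentration row from mean RI through the
#' Barer relation with `n_medium = 1.3337` and `alpha = 0.19`, and dry mass
#' from concentration times volume.
#'
#' @return Tibble with one row per compartment and the same columns as
#'   [compute_stats()] output plus `color`.
#' @examples
#' diatom_reference_panel()
#' @export
diatom_reference_panel <- function() {
  tibble(
    label = c("frustule", "protoplasm", "vacuole", "chloroplast"),
    color = c("black", "green", "blue", "red"),
    ri_min = c(1.3520, 1.3630, 1.3880, 1.4030),
    ri_max = c(1.3570, 1.3810, 1.3950, 1.4360),
    volume_um3 = c(147.4674, 109.0293, 63.3513, 42.5344),
    volume_color_um3 = c(38.4381, 45.6780, 20.8169, 42.5344),
    surface_area_um2 = c(288.5568, 197.5795, 145.0073, 114.9186),
    projected_area_um2 = c(57.2084, 43.5051, 33.1990, 26.5573),
    mean_ri = c(1.3878, 1.3989, 1.4164, 1.4271),
    concentration_pg_per_um3 = c(0.2849, 0.3432, 0.4351, 0.4917),
    dry_mass_pg = c(42.0068, 37.4194, 27.5611, 20.9152),
    dry_mass_color_pg = c(4.5874, 9.8583, 6.6459, 20.9152),
    sphericity = c(0.4678, 0.5586, 0.5300, 0.5128),
    threshold_ri = c(1.3520, 1.3630, 1.3880, 1.4030)
  )
}

#' Self-consistency checks on a printed morphometric panel
#'
#' Recomputes, from the panel's printed values alone, every quantity that is
#' arithmetically determined by the others, and reports the discrepancies:
#'
#' * `sphericity_calc` — Wadell sphericity from printed volume and surface
#'   area;
#' * `concentration_calc` — Barer concentration from printed mean RI;
#' * `dry_mass_calc` — printed concentration times printed volume;
#' * `implied_band_ri` — mean in-band RI implied by printed in-band dry mass
#'   and volume, with `implied_in_band` indicating whether it falls inside
#'   the printed `[Min RI, Max RI]` interval.
#'
#' @param panel A panel tibble (default [diatom_reference_panel()]).
#' @param medium A [medium_model()].
#' @return Tibble with one row per compartment: recomputed values, absolute
#'   errors against the printed ones, and the in-band indicator.
#' @examples
#' check_reference_panel()
#' @export
check_reference_panel <- function(panel = diatom_reference_panel(),
                                  medium = medium_model()) {
  stopifnot(is.data.frame(panel))
  dplyr::transmute(
    panel,
    label = .data$label,
    sphericity_calc = sphericity(.data$volume_um3, .data$surface_area_um2),
    sphericity_abs_err = abs(.data$sphericity_calc - .data$sphericity),
    concentration_calc = concentration_from_ri(.data$mean_ri, medium),
    concentration_abs_err =
      abs(.data$concentration_calc - .data$concentration_pg_per_um3),
    dry_mass_calc = .data$concentration_pg_per_um3 * .data$volume_um3,
    dry_mass_abs_err = abs(.data$dry_mass_calc - .data$dry_mass_pg),
    implied_band_ri = implied_band_mean_ri(.data$dry_mass_color_pg,
                                           .data$volume_color_um3, medium),
    implied_in_band = .data$implied_band_ri >= .data$ri_min &
      .data$implied_band_ri <= .data$ri_max
  )
}
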