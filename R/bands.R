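#' RI bands: labelled closed refractive-index intervals
#'
#' A band selects the voxels of one subcellular compartment by a closed RI
#' interval: a voxel belongs to the band iff `ri_min <= RI <= ri_max`
#' (both endpoints inclusive). `default_bands()` returns the four-band
#' configuration for a living *Cylindrotheca* sp. diatom measured by
#' holotomography: frustule (black), protoplasm (green), vacuole membrane
#' (blue) and chloroplast (red). Gaps between bands are deliberately
#' unassigned — voxels there belong to no compartment.
#'
#' @param label Compartment name.
#' @param ri_min,ri_max Closed interval bounds, dimensionless RI,
#'   `ri_min < ri_max`.
#' @param color Display colour string.
#' @return A tibble with columns `label`, `ri_min`, `ri_max`, `color`;
#'   one row per band.
#' @examples
#' default_bands()
#' ri_band("bead", 1.58, 1.62)
#' @export
ri_band <- function(label, ri_min, ri_max, color = NA_character_) {
  if (!is.numeric(ri_min) || !is.numeric(ri_max) || ri_min >= ri_max) {
    abort("`ri_min` must be strictly less than `ri_max`")
  }
  tibble(label = as.character(label), ri_min = as.double(ri_min),
         ri_max = as.double(ri_max), color = as.character(color))
}

#' @rdname ri_band
#' @export
default_bands <- function() {
  dplyr::bind_rows(
    ri_band("frustule",    1.352, 1.357, "black"),
    ri_band("protoplasm",  1.363, 1.381, "green"),
    ri_band("vacuole",     1.388, 1.395, "blue"),
    ri_band("chloroplast", 1.403, 1.436, "red")
  )
}

#' Read or write a band-configuration file
#'
#' Band configurations are YAML or JSON documents holding a list of
#' `{label, ri_min, ri_max, color}` records. A copy of the default
#' four-band configuration ships in
#' `system.file("extdata", "default_bands.yaml", package = "ritomo")`.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @param bands A band tibble as returned by [default_bands()].
#' @return `read_bands()`: a validated band tibble. `write_bands()`: `path`,
#'   invisibly.
#' @export
read_bands <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
          else abort("band configuration must be .yaml/.yml or .json")
  bands <- purrr::map_dfr(recs, function(r) {
    ri_band(r$label, r$ri_min, r$ri_max, r$color %||% NA_character_)
  })
  validate_bands(bands)
}

#' @rdname read_bands
#' @export
write_bands <- function(bands, path) {
  validate_bands(bands)
  recs <- purrr::pmap(bands, function(label, ri_min, ri_max, color) {
    r <- list(label = label, ri_min = ri_min, ri_max = ri_max)
    if (!is.na(color)) r$color <- color
    r
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(recs, path)
  else if (ext == "json") jsonlite::write_json(recs, path, auto_unbox = TRUE)
  else abort("band configuration must be .yaml/.yml or .json")
  invisible(path)
}

validate_bands <- function(bands) {
  stopifnot(is.data.frame(bands), nrow(bands) > 0L)
  required <- c("label", "ri_min", "ri_max")
  if (!all(required %in% names(bands))) {
    abort("bands need columns label, ri_min, ri_max")
  }
  if (anyDuplicated(bands$label)) abort("band labels must be unique")
  if (any(bands$ri_min >= bands$ri_max)) {
    abort("every band needs ri_min < ri_max")
  }
  if (nrow(bands) > 1L) {
    for (i in seq_len(nrow(bands) - 1L)) {
      for (j in seq(i + 1L, nrow(bands))) {
        if (bands$ri_min[j] <= bands$ri_max[i] &&
            bands$ri_min[i] <= bands$ri_max[j]) {
          warn(sprintf("bands '%s' and '%s' overlap",
                       bands$label[i], bands$label[j]))
        }
      }
    }
  }
  bands
}

as_band_row <- function(band) {
  if (is.data.frame(band)) {
    if (nrow(band) != 1L) abort("expected exactly one band")
    return(band)
  }
  ri_band(band$label %||% "band", band$ri_min, band$ri_max,
          band$color %||% NA_character_)
}
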