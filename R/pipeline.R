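#' Run the full per-band analysis on a tomogram
#'
#' For each band: [segment_compartment()] then [compute_stats()]. The run is
#' deterministic given its inputs — no stage draws random numbers. A band
#' matching no voxels yields an all-`NA` statistics row with a warning rather
#' than a failure (a real tomogram may legitimately miss a compartment).
#'
#' @param x An [ri_tomogram()] or a path readable by [read_tomogram()].
#' @param bands Band tibble (default [default_bands()]).
#' @param medium A [medium_model()].
#' @param closing_radius,connectivity,keep_largest Segmentation parameters,
#'   see [segment_compartment()].
#' @param projection_axis Axis for [projected_area()].
#' @param smooth_iterations Taubin iterations for [surface_area()].
#' @param dataset,spacing Passed to [read_tomogram()] when `x` is a path.
#' @param verbose Log per-stage voxel counts with [message()].
#' @return An object of class `ri_analysis`: list with `stats` (tibble, one
#'   row per band), `masks` (named list of `compartment_masks`, `NULL` for
#'   empty bands), `bands`, `medium`, `params`.
#' @examples
#' ph <- make_bead_phantom(radius_um = 1, shape = c(24, 24, 24),
#'                         spacing = c(0.1, 0.1, 0.1))
#' fit <- run_analysis(ph$tomogram, bands = ri_band("bead", 1.58, 1.62))
#' report_table(fit)
#' @export
run_analysis <- function(x, bands = default_bands(), medium = medium_model(),
                         closing_radius = 1L, connectivity = 26L,
                         keep_largest = TRUE, projection_axis = "z",
                         smooth_iterations = 100L,
                         dataset = "Data/3D", spacing = NULL,
                         verbose = FALSE) {
  tomo <- if (is_ri_tomogram(x)) x
          else read_tomogram(x, dataset = dataset, spacing = spacing)
  assert_valid_tomogram(tomo)
  bands <- validate_bands(bands)
  say <- function(...) if (verbose) inform(sprintf(...))

  res <- purrr::map(seq_len(nrow(bands)), function(i) {
    band <- bands[i, ]
    masks <- tryCatch(
      segment_compartment(tomo, band, closing_radius, connectivity,
                          keep_largest),
      error = function(e) {
        if (grepl("band matched no voxels", conditionMessage(e))) {
          warn(sprintf("band '%s' matched no voxels; empty column",
                       band$label))
          return(NULL)
        }
        stop(e)
      })
    if (is.null(masks)) {
      return(list(masks = NULL, stats = empty_stats_row(band)))
    }
    say("band '%s': %d in-band voxels, %d enclosed", band$label,
        sum(masks$band_mask), sum(masks$enclosed_mask))
    list(masks = masks,
         stats = compute_stats(tomo, masks, medium, projection_axis,
                               smooth_iterations))
  })

  structure(
    list(
      stats = dplyr::bind_rows(purrr::map(res, "stats")),
      masks = stats::setNames(purrr::map(res, "masks"), bands$label),
      bands = bands,
      medium = medium,
      params = list(closing_radius = closing_radius,
                    connectivity = connectivity,
                    keep_largest = keep_largest,
                    projection_axis = projection_axis,
                    smooth_iterations = smooth_iterations)
    ),
    class = "ri_analysis"
  )
}

empty_stats_row <- function(band) {
  tibble(
    label = band$label, ri_min = band$ri_min, ri_max = band$ri_max,
    volume_um3 = NA_real_, volume_color_um3 = NA_real_,
    surface_area_um2 = NA_real_, projected_area_um2 = NA_real_,
    mean_ri = NA_real_, concentration_pg_per_um3 = NA_real_,
    dry_mass_pg = NA_real_, dry_mass_color_pg = NA_real_,
    sphericity = NA_real_, threshold_ri = band$ri_min
  )
}

#' @export
print.ri_analysis <- function(x, ...) {
  cat(sprintf("<ri_analysis> %d bands\n", nrow(x$stats)))
  print(report_table(x))
  invisible(x)
}

report_rows <- c(
  "Min RI" = "ri_min",
  "Max RI" = "ri_max",
  "Volume (um³)" = "volume_um3",
  "Volume of color (um³)" = "volume_color_um3",
  "Surface area (um²)" = "surface_area_um2",
  "Projected area (um²)" = "projected_area_um2",
  "Mean RI" = "mean_ri",
  "Concentration (pg/um³)" = "concentration_pg_per_um3",
  "Dry mass (pg)" = "dry_mass_pg",
  "Dry mass of color (pg)" = "dry_mass_color_pg",
  "Sphericity" = "sphericity",
  "Threshold RI" = "threshold_ri"
)

#' Morphometric report table
#'
#' Pivots per-band statistics into the panel layout: one fixed row per
#' statistic (with units), one column per band, rows ordered Min RI, Max RI,
#' Volume, Volume of color, Surface area, Projected area, Mean RI,
#' Concentration, Dry mass, Dry mass of color, Sphericity, Threshold RI.
#'
#' @param x An `ri_analysis` or its `stats` tibble.
#' @return A tibble: column `statistic` plus one numeric column per band.
#' @export
report_table <- function(x) {
  stats <- if (inherits(x, "ri_analysis")) x$stats else x
  stopifnot(is.data.frame(stats), nrow(stats) > 0L)
  cols <- lapply(stats$label, function(lab) {
    row <- stats[stats$label == lab, ]
    vapply(unname(report_rows), function(f) row[[f]], numeric(1),
           USE.NAMES = FALSE)
  })
  out <- tibble(statistic = names(report_rows))
  for (i in seq_along(cols)) out[[stats$label[i]]] <- cols[[i]]
  out
}

#' Write a report table to CSV or JSON
#'
#' CSV values are printed with exactly 4 decimals (the panel's conventional
#' precision); JSON keeps full float precision for programmatic use.
#'
#' @param table A report table from [report_table()] (or an `ri_analysis`).
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, format = c("auto", "csv", "json")) {
  if (inherits(table, "ri_analysis")) table <- report_table(table)
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "csv") "csv" else if (ext == "json") "json"
              else abort("cannot infer report format; use .csv or .json")
  }
  if (format == "csv") {
    fmt <- table
    for (j in seq_along(fmt)[-1]) fmt[[j]] <- sprintf("%.4f", fmt[[j]])
    utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(table, path, dataframe = "columns", digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path JSON file written by [write_report()].
#' @return The report tibble.
#' @export
read_report <- function(path) {
  as_tibble(jsonlite::fromJSON(path))
}

#' @method tidy ri_analysis
#' @export
tidy.ri_analysis <- function(x, ...) {
  tidyr::pivot_longer(x$stats, -c("label"),
                      names_to = "statistic", values_to = "value")
}

#' @method glance ri_analysis
#' @export
glance.ri_analysis <- function(x, ...) {
  tibble(
    n_bands = nrow(x$stats),
    n_empty = sum(is.na(x$stats$volume_um3)),
    total_volume_um3 = sum(x$stats$volume_um3, na.rm = TRUE),
    total_dry_mass_pg = sum(x$stats$dry_mass_pg, na.rm = TRUE),
    n_medium = x$medium$n_medium,
    alpha = x$medium$alpha
  )
}
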