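#' Refractive-index tomogram
#'
#' Container for a 3D grid of dimensionless refractive-index (RI) values with
#' physical voxel spacing. Axis order is fixed as (z, y, x) with z the
#' optical/axial axis; the first array index runs along z. Spacing follows the
#' same order, in micrometres.
#'
#' @param values 3D numeric array of refractive indices, dimension (nz, ny, nx).
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in micrometres, all
#'   strictly positive.
#' @param metadata Named list of free-form metadata; values are coerced to
#'   character (e.g. `list(wavelength_nm = "532", medium_ri = "1.3337")`).
#'
#' @return An object of class `ri_tomogram`: a list with elements `values`,
#'   `spacing` (named `dz`, `dy`, `dx`) and `metadata`.
#' @seealso [validate_tomogram()], [read_tomogram()], [write_tomogram()]
#' @examples
#' tomo <- ri_tomogram(array(1.3337, c(4, 8, 8)), spacing = c(0.36, 0.115, 0.115))
#' tomo
#' @export
ri_tomogram <- function(values, spacing, metadata = list()) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    abort("`values` must be a 3D array (z, y, x).")
  }
  if (!is.numeric(values)) abort("`values` must be numeric.")
  if (!is.numeric(spacing) || length(spacing) != 3L) {
    abort("`spacing` must be a numeric vector (dz, dy, dx).")
  }
  if (anyNA(spacing) || any(spacing <= 0)) {
    abort("`spacing` components must be strictly positive.")
  }
  if (!is.list(metadata)) abort("`metadata` must be a list.")
  if (length(metadata) && is.null(names(metadata))) {
    abort("`metadata` must be named.")
  }
  storage.mode(values) <- "double"
  structure(
    list(
      values = values,
      spacing = stats::setNames(as.double(spacing), c("dz", "dy", "dx")),
      metadata = lapply(metadata, as.character)
    ),
    class = "ri_tomogram"
  )
}

#' @export
print.ri_tomogram <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ri_tomogram> %d x %d x %d voxels (z,y,x) @ (%.4g, %.4g, %.4g) um\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  fov <- d * x$spacing
  cat(sprintf("  field of view: %.2f x %.2f x %.2f um\n", fov[1], fov[2], fov[3]))
  v <- x$values[is.finite(x$values)]
  if (length(v)) {
    cat(sprintf("  RI range: [%.4f, %.4f], mean %.4f\n",
                min(v), max(v), mean(v)))
  }
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ri_tomogram <- function(x) dim(x$values)

is_ri_tomogram <- function(x) inherits(x, "ri_tomogram")

#' Validate a refractive-index tomogram
#'
#' Checks the tomogram invariants and reports findings rather than raising
#' conditions. Error-level findings: non-finite values, non-positive spacing,
#' fewer than 2 voxels along an axis. Values outside the physically plausible
#' RI interval \[1.0, 2.0\] for aqueous samples are a warning-level finding
#' with the offending voxel count.
#'
#' @param tomo An [ri_tomogram()].
#' @return A tibble with columns `severity` (`"error"`/`"warning"`),
#'   `message`, and `count` (number of offending voxels, `NA` where not
#'   applicable). Zero rows when all invariants hold.
#' @examples
#' t1 <- ri_tomogram(array(1.4, c(4, 4, 4)), c(0.1, 0.1, 0.1))
#' validate_tomogram(t1)   # no findings
#' @export
validate_tomogram <- function(tomo) {
  stopifnot(is_ri_tomogram(tomo))
  findings <- list()
  add <- function(severity, message, count = NA_integer_) {
    findings[[length(findings) + 1L]] <<-
      tibble(severity = severity, message = message, count = as.integer(count))
  }
  v <- tomo$values
  n_nan <- sum(is.nan(v))
  n_inf <- sum(is.infinite(v))
  n_na <- sum(is.na(v)) - n_nan
  if (n_nan + n_inf + n_na > 0L) {
    add("error",
        sprintf("non-finite values: NaN count %d, Inf count %d, NA count %d",
                n_nan, n_inf, n_na),
        n_nan + n_inf + n_na)
  }
  if (any(tomo$spacing <= 0)) {
    add("error", "voxel spacing must be strictly positive on every axis")
  }
  if (any(dim(v) < 2L)) {
    add("error", "grid must have at least 2 voxels along every axis")
  }
  out_of_range <- sum(v < 1.0 | v > 2.0, na.rm = TRUE)
  if (out_of_range > 0L) {
    add("warning",
        sprintf("%d voxels outside the physical RI range [1.0, 2.0]",
                out_of_range),
        out_of_range)
  }
  if (!length(findings)) {
    return(tibble(severity = character(), message = character(),
                  count = integer()))
  }
  dplyr::bind_rows(findings)
}

# internal: stop on error-level findings, surface warnings
assert_valid_tomogram <- function(tomo) {
  f <- validate_tomogram(tomo)
  err <- f[f$severity == "error", ]
  if (nrow(err)) {
    abort(paste0("invalid tomogram: ", paste(err$message, collapse = "; ")))
  }
  for (m in f$message[f$severity == "warning"]) warn(m)
  invisible(tomo)
}
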