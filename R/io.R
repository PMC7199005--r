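#' Read a 3D RI tomogram from TIFF or HDF5
#'
#' Multi-page float TIFF stacks (one page per z slice) and HDF5 containers
#' with a 3D numeric dataset are supported. Voxel spacing is resolved in this
#' order: explicit `spacing` argument, then file metadata, otherwise an error
#' — spacing is never silently assumed, since every downstream statistic
#' carries physical units.
#'
#' TIFF spacing metadata is read from the ImageDescription
#' (`spacing=<dz_um>` plus exact `dy=`/`dx=` entries written by
#' [write_tomogram()]) with X/YResolution tags (pixels per micrometre) as a
#' fallback for the lateral axes. HDF5 spacing is read from the
#' `element_size_um` attribute of the dataset.
#'
#' @param path File to read.
#' @param format `"auto"` (by extension), `"tiff"` or `"hdf5"`.
#' @param dataset Dataset path inside an HDF5 container (default `"Data/3D"`).
#' @param spacing Optional `(dz, dy, dx)` override in micrometres; takes
#'   precedence over file metadata.
#' @return An [ri_tomogram()].
#' @export
read_tomogram <- function(path, format = c("auto", "tiff", "hdf5"),
                          dataset = "Data/3D", spacing = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- resolve_format(path, format)
  if (format == "tiff") read_tomogram_tiff(path, spacing)
  else read_tomogram_hdf5(path, dataset, spacing)
}

#' Write a 3D RI tomogram to TIFF or HDF5
#'
#' TIFF output is an uncompressed multi-page float32 stack with spacing in the
#' X/YResolution tags (pixels per micrometre) and in the ImageDescription
#' (`spacing=<dz_um>;dy=...;dx=...;metadata=<JSON>`). HDF5 output stores the
#' grid (float64 by default, float32 on request) at `dataset`, with
#' `element_size_um` and a JSON `metadata` attribute.
#'
#' @param tomo An [ri_tomogram()].
#' @param path Output file; its parent directory must exist.
#' @param format `"auto"` (by extension), `"tiff"` or `"hdf5"`.
#' @param dataset Dataset path for HDF5 output.
#' @param dtype HDF5 storage type, `"double"` (default) or `"float"`.
#' @return `path`, invisibly.
#' @export
write_tomogram <- function(tomo, path, format = c("auto", "tiff", "hdf5"),
                           dataset = "Data/3D", dtype = c("double", "float")) {
  stopifnot(is_ri_tomogram(tomo))
  format <- match.arg(format)
  dtype <- match.arg(dtype)
  if (!dir.exists(dirname(path))) {
    abort(sprintf("parent directory does not exist: %s", dirname(path)))
  }
  format <- resolve_format(path, format)
  if (format == "tiff") {
    write_tiff_float32(tomo$values, tomo$spacing, tomo$metadata, path)
  } else {
    write_hdf5_grid(tomo$values, path, dataset,
                    spacing = tomo$spacing, metadata = tomo$metadata,
                    dtype = dtype)
  }
  invisible(path)
}

resolve_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("h5", "hdf5", "he5", "hdf")) return("hdf5")
  abort(sprintf("cannot infer container format from extension '.%s'", ext))
}

# ---- TIFF ------------------------------------------------------------------

read_tomogram_tiff <- function(path, spacing_override) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, function(p) length(dim(p)) == 2L, logical(1)))) {
    abort("TIFF pages are not single-channel 2D slices; not a 3D RI stack")
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  nz <- length(pages)
  values <- array(NA_real_, c(nz, ny, nx))
  for (z in seq_len(nz)) values[z, , ] <- pages[[z]]

  desc <- attr(pages[[1]], "description")
  meta <- list()
  file_spacing <- NULL
  if (!is.null(desc)) {
    dz <- desc_field(desc, "spacing")
    dy <- desc_field(desc, "dy")
    dx <- desc_field(desc, "dx")
    mjson <- sub(".*metadata=", "", desc)
    if (grepl("metadata=", desc) && nzchar(mjson)) {
      meta <- tryCatch(as.list(jsonlite::fromJSON(mjson)), error = function(e) list())
    }
    if (!is.na(dz)) {
      if (is.na(dy) || is.na(dx)) {
        res <- lateral_from_resolution(pages[[1]])
        dy <- res[1]; dx <- res[2]
      }
      if (!is.na(dy) && !is.na(dx)) file_spacing <- c(dz, dy, dx)
    }
  }
  spacing <- spacing_override %||% file_spacing
  if (is.null(spacing)) {
    abort("no voxel spacing in file metadata and no `spacing` override given")
  }
  ri_tomogram(values, spacing, meta)
}

desc_field <- function(desc, key) {
  m <- regmatches(desc, regexec(paste0("(^|;)", key, "=([0-9.eE+-]+)"), desc))[[1]]
  if (length(m) < 3L) NA_real_ else as.numeric(m[3])
}

lateral_from_resolution <- function(page) {
  xr <- attr(page, "x.resolution"); yr <- attr(page, "y.resolution")
  unit <- attr(page, "resolution.unit") %||% "none"
  if (is.null(xr) || is.null(yr) || !identical(unit, "none")) {
    return(c(NA_real_, NA_real_))
  }
  c(1 / yr, 1 / xr)  # resolutions are pixels per micrometre
}

# Minimal uncompressed multi-page float32 grayscale TIFF writer. The installed
# TIFF writer cannot store samples outside [0, 1] or description/resolution
# tags, so physical-RI stacks are written here directly (little-endian,
# one strip per page, SampleFormat = IEEE float).
write_tiff_float32 <- function(values, spacing, metadata, path) {
  d <- dim(values)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  meta_json <- as.character(jsonlite::toJSON(metadata, auto_unbox = TRUE))
  desc <- sprintf("spacing=%.17g;dy=%.17g;dx=%.17g;metadata=%s",
                  spacing[1], spacing[2], spacing[3], meta_json)
  desc_count <- nchar(desc, type = "bytes") + 1L  # includes NUL terminator
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  if (length(desc_raw) %% 2L) desc_raw <- c(desc_raw, as.raw(0L))  # pad only

  page_bytes <- as.integer(ny) * as.integer(nx) * 4L
  data_off <- 8L
  desc_off <- data_off + nz * page_bytes
  res_off <- desc_off + length(desc_raw)        # two RATIONALs, 8 bytes each
  ifd_off <- res_off + 16L
  n_tags <- function(z) if (z == 1L) 14L else 13L
  ifd_size <- function(z) 2L + 12L * n_tags(z) + 4L
  ifd_offsets <- ifd_off + cumsum(c(0L, vapply(seq_len(nz), ifd_size, integer(1))))

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_offsets[1])
  for (z in seq_len(nz)) {
    writeBin(as.numeric(t(values[z, , ])), con, size = 4, endian = "little")
  }
  writeBin(desc_raw, con)
  # X/YResolution in pixels per micrometre: 1/dx = 1e7 / (dx * 1e7)
  w32(10000000L); w32(as.integer(round(spacing[3] * 1e7)))
  w32(10000000L); w32(as.integer(round(spacing[2] * 1e7)))

  tag <- function(code, type, count, value, is_offset = FALSE) {
    w16(code); w16(type); w32(count)
    if (type == 3L && !is_offset) { w16(value); w16(0L) } else w32(value)
  }
  for (z in seq_len(nz)) {
    w16(n_tags(z))
    tag(256L, 4L, 1L, nx)                       # ImageWidth
    tag(257L, 4L, 1L, ny)                       # ImageLength
    tag(258L, 3L, 1L, 32L)                      # BitsPerSample
    tag(259L, 3L, 1L, 1L)                       # Compression: none
    tag(262L, 3L, 1L, 1L)                       # Photometric: black is zero
    if (z == 1L) tag(270L, 2L, desc_count, desc_off, is_offset = TRUE)
    tag(273L, 4L, 1L, data_off + (z - 1L) * page_bytes)  # StripOffsets
    tag(277L, 3L, 1L, 1L)                       # SamplesPerPixel
    tag(278L, 4L, 1L, ny)                       # RowsPerStrip
    tag(279L, 4L, 1L, page_bytes)               # StripByteCounts
    tag(282L, 5L, 1L, res_off, is_offset = TRUE)       # XResolution
    tag(283L, 5L, 1L, res_off + 8L, is_offset = TRUE)  # YResolution
    tag(296L, 3L, 1L, 1L)                       # ResolutionUnit: none
    tag(339L, 3L, 1L, 3L)                       # SampleFormat: IEEE float
    w32(if (z < nz) ifd_offsets[z + 1L] else 0L)
  }
  invisible(path)
}

# ---- HDF5 ------------------------------------------------------------------

read_tomogram_hdf5 <- function(path, dataset, spacing_override) {
  values <- tryCatch(
    rhdf5::h5read(path, dataset),
    error = function(e) abort(sprintf(
      "cannot read dataset '%s' from %s: %s", dataset, path, conditionMessage(e)))
  )
  if (length(dim(values)) != 3L || !is.numeric(values)) {
    abort(sprintf("dataset '%s' is not a 3D numeric array", dataset))
  }
  at <- rhdf5::h5readAttributes(path, dataset)
  file_spacing <- if (!is.null(at$element_size_um)) as.numeric(at$element_size_um)
  meta <- list()
  if (!is.null(at$metadata)) {
    meta <- tryCatch(as.list(jsonlite::fromJSON(as.character(at$metadata))),
                     error = function(e) list())
  }
  spacing <- spacing_override %||% file_spacing
  if (is.null(spacing)) {
    abort("no voxel spacing in file metadata and no `spacing` override given")
  }
  ri_tomogram(array(as.double(values), dim(values)), spacing, meta)
}

write_hdf5_grid <- function(values, path, dataset, spacing, metadata,
                            dtype = "double", storage = "double") {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  parts <- strsplit(dataset, "/", fixed = TRUE)[[1]]
  if (length(parts) > 1L) {
    for (i in seq_len(length(parts) - 1L)) {
      grp <- paste(parts[seq_len(i)], collapse = "/")
      suppressWarnings(try(rhdf5::h5createGroup(path, grp), silent = TRUE))
    }
  }
  h5type <- if (storage == "integer") "H5T_NATIVE_UINT32"
            else if (dtype == "float") "H5T_IEEE_F32LE" else "H5T_IEEE_F64LE"
  rhdf5::h5createDataset(path, dataset, dims = dim(values), H5type = h5type)
  rhdf5::h5write(values, path, dataset)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, dataset)
  rhdf5::h5writeAttribute(as.numeric(spacing), did, "element_size_um")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(metadata, auto_unbox = TRUE)), did, "metadata")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

# ---- label maps and masks --------------------------------------------------

#' Write or read a ground-truth label map (HDF5)
#'
#' Label maps pair a tomogram with per-voxel integer compartment IDs
#' (0 = medium/background). They are stored as an unsigned integer HDF5
#' dataset with a JSON `legend` attribute mapping IDs to compartment names
#' and an `element_size_um` spacing attribute.
#'
#' @param labels 3D integer array of compartment IDs.
#' @param legend Named character vector mapping IDs to labels,
#'   e.g. `c("1" = "bead")`.
#' @param path HDF5 file path.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @param dataset Dataset path (default `"Data/Labels"`).
#' @return `path` invisibly (`write_labelmap`); a list with `labels`,
#'   `legend`, `spacing` (`read_labelmap`).
#' @export
write_labelmap <- function(labels, legend, path, spacing,
                           dataset = "Data/Labels") {
  stopifnot(length(dim(labels)) == 3L)
  ids <- sort(unique(as.integer(labels)))
  ids <- ids[ids != 0L]
  if (!all(as.character(ids) %in% names(legend))) {
    abort("every nonzero label ID must be present in `legend`")
  }
  if (file.exists(path)) unlink(path)
  storage.mode(labels) <- "integer"
  rhdf5::h5createFile(path)
  parts <- strsplit(dataset, "/", fixed = TRUE)[[1]]
  if (length(parts) > 1L) {
    rhdf5::h5createGroup(path, paste(parts[-length(parts)], collapse = "/"))
  }
  rhdf5::h5createDataset(path, dataset, dims = dim(labels),
                         H5type = "H5T_STD_U16LE")
  rhdf5::h5write(labels, path, dataset)
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, dataset)
  rhdf5::h5writeAttribute(as.numeric(spacing), did, "element_size_um")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(as.list(legend), auto_unbox = TRUE)),
    did, "legend")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path, dataset = "Data/Labels") {
  labels <- rhdf5::h5read(path, dataset)
  at <- rhdf5::h5readAttributes(path, dataset)
  legend <- unlist(jsonlite::fromJSON(as.character(at$legend)))
  labels <- array(as.integer(labels), dim(labels))
  list(labels = labels, legend = legend,
       spacing = as.numeric(at$element_size_um))
}

#' Export a binary mask as an 8-bit multi-page TIFF
#'
#' @param mask 3D logical array.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  pages <- lapply(seq_len(dim(mask)[1]), function(z) mask[z, , ] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
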