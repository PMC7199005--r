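# Synthetic holotomography phantoms with voxel-level ground truth. Geometry is
# deterministic; per-voxel RI values are sampled uniformly within each
# compartment's band under the supplied seed, so mean-RI statistics are
# nondegenerate and runs are bit-reproducible.

axis_coords <- function(n, d) (seq_len(n) - (n + 1) / 2) * d

# ellipsoid mask: center and semi-axes in physical (z,y,x) um, grid-centred
# coordinates
ellipsoid_mask <- function(dim, spacing, center_um, semi_um) {
  e1 <- ((axis_coords(dim[1], spacing[1]) - center_um[1]) / semi_um[1])^2
  e2 <- ((axis_coords(dim[2], spacing[2]) - center_um[2]) / semi_um[2])^2
  e3 <- ((axis_coords(dim[3], spacing[3]) - center_um[3]) / semi_um[3])^2
  outer(outer(e1, e2, "+"), e3, "+") <= 1
}

sphere_mask <- function(dim, spacing, center_um, radius_um) {
  ellipsoid_mask(dim, spacing, center_um, rep(radius_um, 3))
}

# spindle along x: circular cross-section whose radius tapers quadratically,
# r(u) = radius_um * (1 - u^2) with u = 2*(x - cx)/length in [-1, 1]
spindle_mask <- function(dim, spacing, center_um, length_um, radius_um) {
  zc <- axis_coords(dim[1], spacing[1]) - center_um[1]
  yc <- axis_coords(dim[2], spacing[2]) - center_um[2]
  xc <- axis_coords(dim[3], spacing[3]) - center_um[3]
  rho2 <- outer(zc^2, yc^2, "+")
  u <- 2 * xc / length_um
  rx2 <- ifelse(abs(u) >= 1, -1, (radius_um * (1 - u^2))^2)
  out <- vapply(seq_len(dim[3]),
                function(k) rho2 <= rx2[k],
                matrix(logical(1), dim[1], dim[2]))
  array(out, dim)
}

erode_ball <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  array(.ball_morph(mask, dim(mask), as.integer(radius), FALSE, FALSE),
        dim(mask))
}

sample_band <- function(n, band) runif(n, band[1], band[2])

#' Calibration bead phantom
#'
#' A polystyrene-like latex bead in aqueous medium: the standard sample used
#' to validate holotomography RI measurements (6 um diameter, manufacturer RI
#' 1.5983). Voxels whose centre lies within `radius_um` of the grid centre
#' take `bead_ri`; all others take `medium_ri`; optional additive Gaussian
#' noise follows. The paired label map marks bead voxels 1.
#'
#' @param radius_um Bead radius in micrometres (default 3, i.e. 6 um
#'   diameter).
#' @param bead_ri Bead refractive index (default 1.5983).
#' @param medium_ri Medium refractive index (default 1.3337).
#' @param shape Grid dimensions `(nz, ny, nx)`.
#' @param spacing Voxel spacing `(dz, dy, dx)` um (default isotropic 0.1).
#' @param noise_sigma Additive zero-mean Gaussian noise, RI units, `>= 0`.
#' @param seed Integer seed for the noise (ignored when `noise_sigma = 0`).
#' @return List with `tomogram` ([ri_tomogram()]), `labels` (3D integer
#'   array) and `legend`.
#' @examples
#' ph <- make_bead_phantom(radius_um = 1, shape = c(24, 24, 24),
#'                         spacing = c(0.1, 0.1, 0.1))
#' all(ph$tomogram$values[ph$labels == 1L] == 1.5983)
#' @export
make_bead_phantom <- function(radius_um = 3, bead_ri = 1.5983,
                              medium_ri = 1.3337,
                              shape = c(72L, 72L, 72L),
                              spacing = c(0.1, 0.1, 0.1),
                              noise_sigma = 0, seed = NULL) {
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0")
  half_extent <- (shape - 1) / 2 * spacing
  if (any(radius_um > half_extent - 2 * spacing)) {
    abort("bead does not fit in the grid with a 2-voxel margin")
  }
  bead <- sphere_mask(shape, spacing, c(0, 0, 0), radius_um)
  values <- array(medium_ri, shape)
  values[bead] <- bead_ri
  tomo <- ri_tomogram(values, spacing,
                      metadata = list(source = "bead_phantom",
                                      medium_ri = medium_ri))
  if (noise_sigma > 0) tomo <- add_noise(tomo, noise_sigma, seed)
  labels <- array(0L, shape)
  labels[bead] <- 1L
  list(tomogram = tomo, labels = labels, legend = c("1" = "bead"))
}

#' Diatom phantom geometry specification
#'
#' Declarative geometry for [make_diatom_phantom()]: an elongated
#' spindle-shaped cell (cylindrotheca-like) whose outermost rind carries the
#' frustule RI band, protoplasm interior, an ellipsoidal vacuole whose thin
#' membrane carries the vacuole band around a lower-RI lumen, and elongated
#' chloroplast lobes rendered last. All positions/sizes in micrometres;
#' offsets are relative to the grid centre, the cell axis runs along x.
#'
#' The lumen band lies *below* the membrane band, so the vacuole's enclosed
#' volume exceeds its in-band volume — the membrane-bounded-cavity geometry
#' that the fill operator must recover. The default chloroplast is a single
#' elongated lobe, so largest-component selection keeps the whole organelle.
#'
#' @param shape Grid dimensions `(nz, ny, nx)`.
#' @param spacing Voxel spacing `(dz, dy, dx)` um.
#' @param medium_ri Medium RI, in \[1.30, 1.40\].
#' @param cell_length_um,cell_radius_um Spindle length and maximal radius.
#' @param rind_voxels Frustule rind thickness in voxels.
#' @param vacuole `NULL` to omit, else list with `offset_um` (x offset) and
#'   `semi_um` (z, y, x semi-axes).
#' @param chloroplasts List (possibly empty) of lists with `offset_um`
#'   ((z, y, x) offset) and `semi_um`.
#' @param bands Named list of RI intervals for `frustule`, `protoplasm`,
#'   `vacuole_membrane`, `vacuole_lumen`, `chloroplast`.
#' @return A list of class `diatom_phantom_spec`.
#' @export
diatom_phantom_spec <- function(
    shape = c(128L, 256L, 256L),
    spacing = c(0.36, 0.115, 0.115),
    medium_ri = 1.3337,
    cell_length_um = 22,
    cell_radius_um = 2.2,
    rind_voxels = 2L,
    vacuole = list(offset_um = 3.5, semi_um = c(1.0, 1.2, 2.8)),
    chloroplasts = list(
      list(offset_um = c(0, 0, -2.5), semi_um = c(0.75, 0.95, 3.6))
    ),
    bands = list(
      frustule = c(1.352, 1.357),
      protoplasm = c(1.363, 1.381),
      vacuole_membrane = c(1.388, 1.395),
      vacuole_lumen = c(1.345, 1.355),
      chloroplast = c(1.403, 1.436)
    )) {
  if (medium_ri < 1.30 || medium_ri > 1.40) {
    abort("`medium_ri` must lie in [1.30, 1.40]")
  }
  spec <- list(shape = as.integer(shape), spacing = as.double(spacing),
               medium_ri = medium_ri, cell_length_um = cell_length_um,
               cell_radius_um = cell_radius_um,
               rind_voxels = as.integer(rind_voxels),
               vacuole = vacuole, chloroplasts = chloroplasts, bands = bands)
  class(spec) <- "diatom_phantom_spec"
  spec
}

#' Read or write a diatom phantom specification (YAML/JSON)
#'
#' @param spec A [diatom_phantom_spec()].
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `read_phantom_spec()`: a `diatom_phantom_spec`;
#'   `write_phantom_spec()`: `path`, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "diatom_phantom_spec"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(spec)
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json") jsonlite::write_json(x, path, auto_unbox = FALSE,
                                               digits = NA)
  else abort("phantom spec must be .yaml/.yml or .json")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE,
                                                  simplifyDataFrame = FALSE)
       else abort("phantom spec must be .yaml/.yml or .json")
  x$vacuole <- if (!is.null(x$vacuole)) {
    list(offset_um = as.numeric(x$vacuole$offset_um),
         semi_um = as.numeric(x$vacuole$semi_um))
  }
  x$chloroplasts <- lapply(x$chloroplasts, function(c.) {
    list(offset_um = as.numeric(c.$offset_um),
         semi_um = as.numeric(c.$semi_um))
  })
  x$bands <- lapply(x$bands, as.numeric)
  do.call(diatom_phantom_spec, x)
}

#' Four-compartment diatom-like phantom
#'
#' Renders the geometry of a [diatom_phantom_spec()] and samples each
#' compartment's RI uniformly within its band (seeded). Components are
#' rendered in order — cell rind, protoplasm, vacuole membrane + lumen,
#' chloroplasts last — with later components overwriting earlier ones.
#' Vacuole and chloroplasts are clipped to the cell interior (one voxel of
#' protoplasm is kept between them and the rind) so compartments are properly
#' nested. The label map records ground truth: 1 frustule rind,
#' 2 protoplasm, 3 vacuole membrane, 4 vacuole lumen, 5 chloroplast.
#'
#' The returned tomogram is noiseless and unblurred; compose with
#' [apply_optical_blur()] and [add_noise()] to emulate instrument data.
#'
#' @param spec A [diatom_phantom_spec()].
#' @param seed Integer seed for the per-voxel RI sampling.
#' @return List with `tomogram`, `labels`, `legend`, `spec`.
#' @examples
#' ph <- make_diatom_phantom(diatom_phantom_spec(
#'   shape = c(32L, 48L, 96L), spacing = c(0.36, 0.23, 0.23),
#'   cell_length_um = 16, cell_radius_um = 1.8,
#'   vacuole = list(offset_um = 2.5, semi_um = c(0.8, 1.0, 2.0)),
#'   chloroplasts = list(list(offset_um = c(0, 0, -2.5),
#'                            semi_um = c(0.6, 0.8, 2.0)))), seed = 7)
#' table(ph$labels)
#' @export
make_diatom_phantom <- function(spec = diatom_phantom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "diatom_phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  body <- spindle_mask(d, sp, c(0, 0, 0), spec$cell_length_um,
                       spec$cell_radius_um)
  if (!any(body)) abort("cell geometry renders no voxels")
  if (any(body[1, , ]) || any(body[d[1], , ]) ||
      any(body[, 1, ]) || any(body[, d[2], ]) ||
      any(body[, , 1]) || any(body[, , d[3]])) {
    abort("cell geometry touches the grid border; enlarge the grid")
  }
  interior <- erode_ball(body, spec$rind_voxels)
  rind <- body & !interior
  # clip organelles to the interior less one voxel so a protoplasm layer
  # always separates them from the rind
  allowed <- erode_ball(body, spec$rind_voxels + 1L)

  labels <- array(0L, d)
  labels[rind] <- 1L
  labels[interior] <- 2L
  if (!is.null(spec$vacuole)) {
    vac <- ellipsoid_mask(d, sp, c(0, 0, spec$vacuole$offset_um),
                          spec$vacuole$semi_um) & allowed
    lumen <- erode_ball(vac, 1L)
    labels[vac & !lumen] <- 3L
    labels[lumen] <- 4L
  }
  for (ch in spec$chloroplasts) {
    m <- ellipsoid_mask(d, sp, ch$offset_um, ch$semi_um) & allowed
    labels[m] <- 5L   # rendered last: overwrites protoplasm/vacuole
  }

  values <- array(spec$medium_ri, d)
  band_of <- c(spec$bands$frustule[1], spec$bands$protoplasm[1],
               spec$bands$vacuole_membrane[1], spec$bands$vacuole_lumen[1],
               spec$bands$chloroplast[1])
  withr::with_seed(seed, {
    for (id in 1:5) {
      idx <- which(labels == id)
      if (!length(idx)) next
      band <- switch(id, spec$bands$frustule, spec$bands$protoplasm,
                     spec$bands$vacuole_membrane, spec$bands$vacuole_lumen,
                     spec$bands$chloroplast)
      values[idx] <- sample_band(length(idx), band)
    }
  })
  tomo <- ri_tomogram(values, sp,
                      metadata = list(source = "diatom_phantom",
                                      medium_ri = spec$medium_ri,
                                      seed = seed))
  list(tomogram = tomo, labels = labels,
       legend = c("1" = "frustule", "2" = "protoplasm",
                  "3" = "vacuole_membrane", "4" = "vacuole_lumen",
                  "5" = "chloroplast"),
       spec = spec)
}

#' Anisotropic optical blur
#'
#' Convolves the tomogram with an anisotropic Gaussian point-spread model:
#' per-axis standard deviation `fwhm / (2 sqrt(2 ln 2))` converted to voxels,
#' axial FWHM applied along z and lateral FWHM along y and x. Defaults match
#' a holotomography system's theoretical resolution (110 nm lateral, 360 nm
#' axial). Boundaries are treated as constant medium RI, so the total RI
#' excess of interior objects is conserved. An axis whose requested FWHM is
#' below 0.1 voxel is skipped with a warning.
#'
#' @param tomo An [ri_tomogram()].
#' @param lateral_fwhm,axial_fwhm Full widths at half maximum, micrometres.
#' @param medium_ri Boundary fill value; defaults to the tomogram's
#'   `medium_ri` metadata, else 1.3337.
#' @return Blurred [ri_tomogram()].
#' @export
apply_optical_blur <- function(tomo, lateral_fwhm = 0.110,
                               axial_fwhm = 0.360, medium_ri = NULL) {
  stopifnot(is_ri_tomogram(tomo))
  if (lateral_fwhm <= 0 || axial_fwhm <= 0) abort("FWHMs must be positive")
  medium_ri <- medium_ri %||%
    as.numeric(tomo$metadata$medium_ri %||% 1.3337)
  fwhm <- c(axial_fwhm, lateral_fwhm, lateral_fwhm)
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / tomo$spacing
  skip <- fwhm / tomo$spacing < 0.1
  if (any(skip)) {
    warn(sprintf("FWHM below 0.1 voxel along %s; axis skipped",
                 paste(c("z", "y", "x")[skip], collapse = ", ")))
    sigma_vox[skip] <- 0
  }
  out <- .gauss_blur3(tomo$values, dim(tomo$values), sigma_vox, medium_ri)
  ri_tomogram(array(out, dim(tomo$values)), tomo$spacing, tomo$metadata)
}

#' Additive Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma`
#' (RI units), seeded and reproducible.
#'
#' @param tomo An [ri_tomogram()].
#' @param sigma Noise standard deviation, `>= 0` (0 = identity).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Noisy [ri_tomogram()].
#' @export
add_noise <- function(tomo, sigma, seed = NULL) {
  stopifnot(is_ri_tomogram(tomo))
  if (sigma < 0) abort("`sigma` must be >= 0")
  if (sigma == 0) return(tomo)
  n <- length(tomo$values)
  noise <- if (is.null(seed)) rnorm(n, 0, sigma)
           else withr::with_seed(seed, rnorm(n, 0, sigma))
  ri_tomogram(tomo$values + array(noise, dim(tomo$values)),
              tomo$spacing, tomo$metadata)
}
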