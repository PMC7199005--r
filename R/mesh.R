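#' Triangulated isosurface of a binary mask
#'
#' Meshes the boundary of a voxel mask and optionally smooths it. The mask is
#' padded by one background voxel on all faces so surfaces close, each grid
#' cell is decomposed into six tetrahedra sharing the main diagonal
#' (Freudenthal decomposition — face diagonals agree between neighbouring
#' cells, so the triangulation is watertight), and iso-vertices are placed at
#' midpoints of tetrahedron edges crossing the surface, in physical
#' coordinates.
#'
#' A binary voxel surface is a staircase whose raw mesh area systematically
#' exceeds the area of the smooth surface it discretises (up to ~50% for
#' voxel-face counting, still several percent for a raw midpoint mesh).
#' Taubin lambda/mu smoothing — a shrink-free low-pass filter on vertex
#' positions — removes the staircase while preserving shape, and a per-axis
#' displacement clamp keeps few-voxel meshes from collapsing. With the
#' defaults (100 iterations, clamp 0.45 voxel), digitized balls of radius
#' 10–30 voxels recover their analytic area to ~2.3% and axis-aligned boxes
#' to ~3.5%; these accuracies are asserted in the package's test suite.
#'
#' @param mask 3D logical array.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @param smooth_iterations Taubin iterations (0 = raw staircase mesh).
#' @param lambda,mu Taubin step sizes (`lambda > 0`, `mu < -lambda` for the
#'   shrink-free pass-band).
#' @param clamp_voxels Per-axis bound on each vertex's total displacement, as
#'   a multiple of the voxel pitch on that axis (staircase relief needs about
#'   half a voxel; the bound keeps few-voxel objects from collapsing under
#'   many iterations). `Inf` disables clamping.
#' @return An object of class `ri_mesh`: list with `vertices` (n x 3 matrix,
#'   physical (z, y, x) um), `faces` (m x 3 integer matrix, 1-based) and
#'   `spacing`.
#' @seealso [surface_area()], [write_mesh()]
#' @export
mask_mesh <- function(mask, spacing, smooth_iterations = 100L,
                      lambda = 0.5, mu = -0.53, clamp_voxels = 0.45) {
  check_mask(mask)
  if (!any(mask)) abort("empty mask")
  m <- .mask_mesh(mask, dim(mask), as.double(spacing))
  V <- m$vertices
  F0 <- m$faces
  if (smooth_iterations > 0L) {
    cl <- if (is.finite(clamp_voxels)) clamp_voxels * as.double(spacing)
          else rep(-1, 3)
    V <- .taubin_smooth(V, F0, as.integer(smooth_iterations), lambda, mu, cl)
  }
  structure(list(vertices = V, faces = F0 + 1L,
                 spacing = as.double(spacing)),
            class = "ri_mesh")
}

#' @export
print.ri_mesh <- function(x, ...) {
  cat(sprintf("<ri_mesh> %d vertices, %d triangles, area %.4g um^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Total triangle area of a mesh
#'
#' @param mesh An `ri_mesh` from [mask_mesh()].
#' @return Area in um^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "ri_mesh"))
  .mesh_area(mesh$vertices, mesh$faces - 1L)
}

#' Write a mesh to PLY or STL (ASCII)
#'
#' @param mesh An `ri_mesh`.
#' @param path Output path ending in `.ply` or `.stl`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "ri_mesh"))
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices
  F1 <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(V)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(F1)),
      "property list uchar int vertex_indices", "end_header"), con)
    # PLY convention x,y,z: emit (x, y, z) from our (z, y, x) columns
    writeLines(sprintf("%.6g %.6g %.6g", V[, 3], V[, 2], V[, 1]), con)
    writeLines(sprintf("3 %d %d %d", F1[, 1] - 1L, F1[, 2] - 1L, F1[, 3] - 1L),
               con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines("solid mask", con)
    for (i in seq_len(nrow(F1))) {
      p <- V[F1[i, ], c(3, 2, 1), drop = FALSE]
      writeLines(c(
        "  facet normal 0 0 0", "    outer loop",
        sprintf("      vertex %.6g %.6g %.6g", p[, 1], p[, 2], p[, 3]),
        "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mask", con)
  } else {
    abort("mesh format must be .ply or .stl")
  }
  invisible(path)
}
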