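---
title: "RI-band morphometry of holotomography tomograms: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RI-band morphometry of holotomography tomograms: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ritomo)
```

## The measurement model

Optical diffraction tomography / holotomography reconstructs a 3D map of the
refractive index (RI) of a living cell in its medium, with no staining. Two
physical facts make that map quantitative:

1. **Compartments occupy RI bands.** Different subcellular materials have
   characteristically different optical densities. For a living
   *Cylindrotheca* sp. diatom in seawater-derived medium the measured bands
   are: frustule (silica shell) 1.352–1.357, protoplasm 1.363–1.381, vacuole
   membrane 1.388–1.395, chloroplast 1.403–1.436. Thresholding the tomogram
   with a closed interval `[ri_min, ri_max]` selects one compartment's
   voxels. Gaps between bands are deliberately unassigned.

2. **RI excess is dry mass (Barer relation).** For cellular matter the RI is
   linear in the dry-mass concentration:
   `n = n_medium + alpha * C`, with `alpha ≈ 0.19 mL/g` for protein (the
   specific refractive increment). Inverting voxel-wise and integrating over
   a compartment gives its dry mass in picograms.

From these two ingredients the package computes, per band, the full
morphometric panel: enclosed volume, in-band ("colour") volume, isosurface
area, projected (silhouette) area, mean RI, dry-mass concentration, dry
mass, in-band dry mass, and Wadell sphericity
$\psi = \pi^{1/3}(6V)^{2/3}/A$.

### Volume versus "volume of colour"

A solid compartment (a chloroplast) is entirely in-band, so its enclosed
volume equals its in-band volume. A membrane-bounded compartment (the
vacuole) is different: only the membrane carries the band's RI, the lumen is
optically thinner. The pipeline therefore computes two masks per band:

* the *in-band mask* — cleaned voxels whose RI actually lies in the band;
* the *enclosed mask* — the filled region: background is flood-filled from
  the grid border with 6-connectivity, and any unreachable background is an
  interior cavity that becomes part of the compartment.

The contrast between the two is diagnostic: equal volumes indicate a solid
body, enclosed ≫ colour indicates a membrane around a cavity.

### Why mean RI is taken over the *enclosed* region

The reference panel's frustule column reports a mean RI of 1.3878 — far
above the frustule band's own maximum of 1.357. That is only arithmetically
possible if the averaged region includes the whole enclosed cell interior,
not just the in-band shell voxels. `compute_stats()` therefore averages RI
over the enclosed mask; the in-band voxels contribute instead to the
"dry mass of colour" row, whose implied mean RI
(`n_medium + alpha * m / V`) lands back inside each band — a self-consistency
check shipped as `check_reference_panel()` and exercised by the test suite.

### Parameter defaults

| parameter | default | units | why |
|---|---|---|---|
| `n_medium` | 1.3337 | – | water at green-laser wavelengths; fitting (mean RI, concentration) pairs across all four panel columns recovers this value essentially exactly |
| `alpha` | 0.19 | µm³/pg | the standard protein refractive increment (0.19 mL/g); same fit |
| band intervals | panel values | – | measured bands of the reference specimen; closed (inclusive) at both ends, matching "Threshold RI" = "Min RI" |
| `closing_radius` | 1 | voxels | membranes sit near the optical resolution limit; a 1-voxel closing seals sub-voxel punctures before cavity filling; 0 reproduces pure thresholding |
| `connectivity` | 26 | – | foreground connectivity; the background fill uses 6, the complementary pair that prevents corner leaks |
| `keep_largest` | TRUE | – | seawater fields of view contain debris (fibre-like objects); size ties break deterministically toward the earliest voxel |
| projection axis | z | – | silhouette along the optical axis; configurable |
| blur FWHM | 0.110 / 0.360 | µm | lateral / axial theoretical resolution of the instrument class |

Both `n_medium` and `alpha` are inferred, not quoted: the inference (the
cross-column fit) ships as a test, and both are configurable through
`medium_model()`.

Negative voxel concentrations (RI below the medium) are kept in dry-mass
integrals by default; clamping would bias totals upward. A `clamp_negative`
flag is available.

## Surface area: the staircase problem

A binary voxel surface is a staircase. Its raw mesh area *systematically*
exceeds the area of the smooth surface it discretises — voxel-face counting
overshoots a sphere by ~50%, and even a midpoint isosurface mesh overshoots
by several percent. Since sphericity compares areas against a perfect
sphere, an uncorrected estimator contaminates the panel.

The estimator here:

1. **Mesh**: the mask (padded with one background voxel so surfaces close)
   is decomposed cell-by-cell into six tetrahedra sharing the main diagonal
   (Freudenthal decomposition). Face diagonals agree between neighbouring
   cells, so the triangulation is watertight by construction, with vertices
   at midpoints of tetrahedron edges crossing the surface, in physical
   coordinates.
2. **Smooth**: Taubin λ/µ smoothing (λ = 0.5, µ = −0.53, 100 iterations) — a
   shrink-free low-pass filter on vertex positions that removes the
   staircase without eroding volume.
3. **Clamp**: each vertex's total displacement is bounded to 0.45 voxel per
   axis. Staircase relief needs about half a voxel, so accuracy is
   unaffected, while few-voxel objects can no longer collapse to a point
   under many iterations.

These defaults were calibrated against closed forms only — digitized balls
of radius 10–30 voxels (areas recovered to ≤ 2.3%), an axis-aligned box
(−3.4%), and a single voxel (small positive area) — and the calibration is
frozen into the test suite. Ball sphericities come out at 0.975–0.984,
approaching 1 with radius.

## Morphology conventions

Closing (`close_mask()`) uses the 3×3×3 cube structuring element (the
Chebyshev ball), the dual of 26-connected foreground: a radius-1 Euclidean
(6-neighbourhood) closing provably cannot seal a 1-voxel pinhole in a
1-voxel wall, while the cube element can — and sealing resolution-limit
punctures is the entire purpose of the step. Plain `erode_mask()` /
`dilate_mask()` use the Euclidean digital ball, the natural choice for
geometric rind/interior constructions.

## The synthetic phantoms

No instrument data ships with the package; every pipeline stage is instead
validated against two generators with voxel-level ground truth.

**Bead phantom** (`make_bead_phantom()`): a 6 µm latex bead (manufacturer RI
1.5983) in medium 1.3337, on an isotropic 0.1 µm grid — a typical
reconstruction export pitch; the instrument's anisotropic resolution enters
through the blur model, not the grid. The validation protocol mirrors
instrument practice: blur, add noise, segment at a band around the bead RI,
erode 2 voxels to discard partial-volume shells, and compare the interior
mean RI with the manufacturer value. Over 30 phantoms at noise σ = 0.002
the recovered mean sits within 0.005 of 1.5983 and per-bead sphericity
within 0.03 of 1.

**Diatom phantom** (`make_diatom_phantom()`): a cylindrotheca-like spindle
(default 22 µm long, 2.2 µm maximal radius, on a 128×256×256 grid at
0.36/0.115/0.115 µm — the instrument class's ~59 µm lateral field of view
at desk-sized memory) with:

* a 2-voxel outer rind carrying the frustule band — the phantom reproduces
  the *measured* band structure, not bulk-silica optics;
* protoplasm filling the interior;
* an ellipsoidal vacuole whose 1-voxel membrane carries the vacuole band
  around a lumen at RI 1.345–1.355, *below* the band — encoding the
  membrane-bounded-cavity hypothesis as ground truth so the fill operator
  is testable;
* a single elongated chloroplast lobe, rendered last (render order resolves
  overlaps), kept one protoplasm voxel clear of the rind.

Per-voxel RI is drawn uniformly within each compartment's band under the
supplied seed, so mean-RI statistics are nondegenerate and runs are
bit-reproducible. Cell dimensions are not calibrated to any particular
specimen — the species' numeric dimensions are not published — but the
default spindle volume (~180 µm³) is the right order for the genus.

The optical model is an anisotropic Gaussian blur (FWHM 110 nm lateral /
360 nm axial, σ = FWHM/2.355 per axis, constant-medium boundaries, flux
conserving) plus i.i.d. Gaussian noise. What the phantom does **not**
emulate: missing-cone reconstruction artifacts, speckle and correlated
noise, RI dispersion, frustule birefringence, neighbouring debris touching
the cell. Passing tests therefore demonstrate that the *analysis* is
correct and calibrated, not that any real specimen will be segmented this
cleanly.

## Whole-cell dry mass under degradation

Total dry mass is the most robust statistic: blur conserves the integral of
RI excess and zero-mean noise cancels over tens of thousands of voxels. The
recommended whole-cell mask is a broad band from just above the noise floor
of the medium (1.344 at σ = 0.002) to above the highest compartment band
(1.50), closed, largest component, filled. On the default phantom the dry
mass recovered this way from a blurred noisy tomogram is within ~1–2% of
the noiseless ground truth; narrow single-band masks are *not* suitable for
this purpose because noise punctures an 0.005-wide band.

## Numerical and degenerate-input behaviour

* Closed-interval band semantics: boundary values are in-band on both ends.
* A band matching no voxels is a warning and an `NA` column in
  `run_analysis()` (an error in bare `segment_compartment()`).
* Component-size ties break toward the component containing the smallest
  linear voxel index — raster discovery order, fully deterministic.
* Cavities open to the grid border are *not* filled; the enclosed-minus-band
  difference never touches the border.
* `validate_tomogram()` reports findings (non-finite values, bad spacing,
  degenerate grids, out-of-[1,2] RI) as a tibble rather than raising, so
  callers decide severity; `run_analysis()` stops on error-level findings.
* Voxel spacing is never assumed: explicit argument > file metadata > error.
* TIFF stores float32 (the interoperable norm); HDF5 stores float64 by
  default with a float32 option.

## Known limitations

* Surface areas of objects a few voxels across remain approximate; the
  displacement clamp prevents collapse but cannot restore sub-voxel detail.
* The in-band/enclosed distinction assumes cavities are fully bounded after
  a 1-voxel closing; membranes broken over larger gaps need a larger
  `closing_radius`, at the cost of bridging genuinely separate structures.
* Anisotropic grids (0.36 µm axial pitch) carry a larger axial staircase;
  area estimates on such grids are less accurate than on the isotropic bead
  grid, which is why the bead validation uses the isotropic export pitch.
* The Barer relation uses a single protein-like `alpha`; silica and lipid
  have different increments, so per-compartment dry masses are
  protein-equivalent masses.

## Reproducing the analysis

```{r, eval = FALSE}
ph <- make_diatom_phantom(seed = 7)
tomo <- ph$tomogram |> apply_optical_blur() |> add_noise(0.002, seed = 11)
fit <- run_analysis(tomo)
report_table(fit)
autoplot(fit)
```

`scripts/acceptance.R` re-derives every headline quantity (panel
arithmetic, bead recovery, phantom ground-truth recovery, oracle agreement,
closed-form ball morphometrics) from scratch; problem sizes are the
defaults quoted above (30 beads of 72³ voxels, one 128×256×256 diatom
phantom, 200 oracle grids up to 20³, one radius-20 ball).
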