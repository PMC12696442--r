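---
title: "Designing and measuring TPMS scaffolds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and measuring TPMS scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmscaffold)
```

## The model

A triply periodic minimal surface (TPMS) partitions space into two
interpenetrating labyrinths separated by a smooth surface of zero mean
curvature. In practice the surface is approximated by the zero level set of
a trigonometric *nodal equation* `f(x, y, z)`; this package implements the
Gyroid, Schwarz Diamond and Schoen I-WP fields (see `?nodal_value` for the
exact expressions). Dimensionless coordinates are 2π-periodic and map to
physical ones through the unit-cell edge length `L`: `x = 2πX/L`.

A scaffold is the *skeletal* solid `{f ≥ t}` — one labyrinth, thickened or
thinned by moving the threshold `t` — generated inside a printable domain
(by default the Ø8 mm × 3 mm cylindrical compression-specimen format). A
*sheet* solid `{|f| ≤ t}`, a shell straddling the surface, is also offered;
skeletal is the default because it is the common choice for stiff
load-bearing scaffolds and makes porosity monotone increasing in `t`,
which the calibration exploits. The mode is recorded in every output.

Two properties of the nodal fields anchor the numerical checks throughout
the package:

* Gyroid and Diamond are **odd under point inversion**
  (`f(−p) = −f(p)`), so at `t = 0` the solid occupies exactly half the
  period by symmetry — a closed-form volume fact the voxelizer must
  reproduce.
* All three fields are 2π-periodic per axis, so volume fractions computed
  on one full period extend to any domain tiled by the cell.

## Porosity calibration

Porosity here always means the **void volume fraction** of the domain
(`target 0.2` ⇒ 80% solid). On a voxel grid with voxels classified by
their centre (matching the binarized-image semantics of the imaging half),
the void fraction `φ(t)` is a monotone step function of the threshold;
`calibrate_threshold()` bisects `t` between the sampled field extrema
until `|φ(t) − target| ≤ tol`.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| unit cell `L` | 2.5 mm | spans ≳3 periods across an 8 mm specimen and yields sub-millimetre pore openings, the regime of interest for cartilage scaffolds; fully configurable |
| voxel pitch | 40 µm | ~62 voxels per cell: porosity is grid-stable to well under half a percentage point, and one calibration takes seconds; 13.69 µm is available to mirror scanner-scale reconstruction |
| tolerance | 1e-3 on φ | an order of magnitude tighter than the ±0.5-point design-reproduction criterion |
| max iterations | 60 | bisection gains one bit per step; 60 exhausts double precision |

With ~2.4 million in-domain voxels the granularity of `φ` is ~4e-7, far
below the tolerance, so bisection always terminates in well under 60
iterations (typically 7–25). Targets outside the achievable range at the
given resolution raise an error reporting the bracket rather than
silently clipping.

```{r calibrate}
cal <- calibrate_threshold("gyroid", domain_cylinder(8, 3),
                           target = 0.2, pitch = 40)
cal
```

A seed-free Monte-Carlo cross-check (`mc_solid_fraction()`, default seed
0, 10^6 points, standard error ≈ 5e-4) integrates the same indicator
without any grid and is used throughout the tests as the independent
volume oracle.

## Mesh export

`extract_surface()` runs marching tetrahedra (a Kuhn 6-tet decomposition
of each grid cube; the split shares face diagonals between neighbouring
cubes, so the triangulation is combinatorially watertight by
construction). Domain capping is done *inside the scalar field*: the
level-set field is min-combined with the signed distance to the domain
boundary on a grid padded by one exterior layer, so the cylinder barrel
and end faces emerge as part of the isosurface in a single pass — no
post-hoc hole filling. Triangles are oriented outward (solid → void), and
`mesh_volume()` (divergence-theorem sum) is positive for a correctly
oriented mesh; it refuses non-watertight input, naming the open-edge
count.

Linear interpolation places each vertex on its grid edge, so mesh volume
converges to the voxel-counted volume at first order in the pitch: the
test suite holds the relative gap under 5% at `L/32` and under 2% at
`L/64`. Binary STL (float32, mm, unlabeled per convention) is the default
dialect for printer compatibility; ASCII is available for inspection.

## The synthetic imaging model

`render_slices()` cuts the voxel model perpendicular to the cylinder axis,
one binary image per voxel layer, emulating the reconstructed axial stacks
of a desktop micro-CT workflow (isotropic voxels; scanner-scale
13.69 µm pitch supported). Rendering is **three-valued** — solid, pore,
outside-domain — and the exterior is collapsed away only when a region of
interest is applied, so background air can never inflate porosity; this
mirrors the role of the fixed ROI in the physical workflow.

`degrade()` emulates reconstruction smoothing: Gaussian blur (EBImage)
followed by re-thresholding, plus optional seeded speckle noise. It is the
stress-test knob for the morphometry, not a physics simulation: beam
hardening, ring artifacts and detector noise are scanner-side effects out
of scope, which is the main respect in which passing tests on synthetic
stacks do *not* certify behaviour on raw scanner output. Because the
simulated stacks are already binary, the segmentation-threshold choice of
a real workflow is likewise not modelled.

`make_phantom()` constructs stacks with pixel-exact ground truth (single
pores, circular channel arrays, checkerboards) used as fixtures wherever
a closed-form answer is needed.

## Morphometry

`slice_porosity()` is pore pixels over total measured pixels inside the
ROI. "Total scaffold area" is read as the whole ROI cross-section, not
the solid phase alone: only that reading keeps porosity in [0, 1] and
matches reported porosities near 20% for 20%-porosity designs. The
measured region is ROI ∩ domain, so exterior background is excluded from
both numerator and denominator.

`label_pores()` labels connected components of the pore phase (two-pass
flood fill in C++; connectivity 8 by default, the particle-analysis
convention, with 4 available), discards components below `min_size_px`
(default 4 px — a noise filter; the upstream workflow states the
existence of the threshold but not its value), and computes
`ECD = 2√(A/π)` from the physical pixel area. Components touching the
boundary of the measured region are flagged rather than dropped: at 20%
porosity the pore network is one large connected opening in many slices,
so excluding boundary-touching pores would discard most of the pore area;
a flag lets the user choose. Standard deviations use the sample (n−1)
denominator and are `NA` below two observations; an empty pore phase
yields `n_pores = 0`, not an error.

```{r phantom}
ph <- make_phantom("circular_channels", image_px = c(400, 400),
                   pixel_size = 10, diameter_um = 400, n_channels = 4)
glance(pore_stats(ph))
```

## Comparing geometries

`pipeline_compare()` runs design → slicing → morphometry for several
geometries at one matched cell size and porosity and ranks mean ECD. Two
caveats are built into how the result is presented. First, the ECD
ordering is checked for *grid convergence* (same strict ranking at two
pitches) before it is trusted. Second, the physical study this emulates
did not report its per-geometry unit-cell sizes, so absolute ECD values
cannot be reproduced, only the within-package comparison at matched cell
size; the computed ranking (Gyroid largest, then Diamond, then I-WP, at
equal `L` and φ) is reported as this package's result and happens to
agree with the measured ordering, but it is not asserted as ground truth.

## Numerical choices and edge cases

* Voxels are classified by centre point, with no partial-volume
  weighting — consistent with binarized-image semantics downstream, and
  the reason slice porosity over an undegraded stack equals the 3D void
  fraction *exactly* when the ROI covers the whole domain.
* Bisection on a step function converges to a jump point; the returned
  `realized` porosity is always re-derivable from the returned threshold
  (`void_fraction(solidify(field, t))`), which the tests assert.
* `f = t` exactly is solid (`≥`); ties are therefore deterministic.
* Degenerate inputs: empty domain masks, empty solids, empty ROIs, and
  pore-free stacks each produce a specific error or sentinel rather than
  propagating NaNs.
* Grid sizes: design-time work uses 40–100 µm pitches (seconds per
  calibration); the two-resolution convergence checks run at 50 and
  25 µm, and unit-cell studies at `L/32` and `L/64`. These sizes were
  chosen as the coarsest grids whose discretization error sits an order
  of magnitude below the tolerances they are tested against.

## Known limitations

* No graded or hybrid TPMS, non-cubic cells, or lattice distortions; no
  mechanical property prediction.
* The imaging model is geometric, not radiometric (no beam hardening,
  ring artifacts, or grey-level segmentation).
* ECD is a 2D proxy for pore-opening size; no 3D pore-network extraction
  or sphere-fitting pore size is attempted.
* Statistical comparison across geometries is descriptive (mean ± SD and
  rank); significance testing belongs to physical replicates, which an
  in-silico pipeline cannot supply.
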