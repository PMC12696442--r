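# tpmscaffold

Digital design and image-based morphometry of triply periodic minimal
surface (TPMS) scaffolds for tissue engineering.

TPMS architectures — here the **Gyroid**, **Schwarz Diamond** and **Schoen
I-WP** — are popular cell-scaffold geometries because their porous networks
are smooth, fully interconnected and free of sharp edges. A scaffold is
designed by thresholding the surface's trigonometric *nodal equation*

```
Gyroid:   f(x,y,z) = cos x sin y + sin x cos z + cos y sin z
Diamond:  f(x,y,z) = sin x sin y sin z + sin x cos y cos z + cos x sin y cos z + cos x cos y sin z
I-WP:     f(x,y,z) = 2 (cos x cos y + cos x cos z + cos y cos z) − (cos 2x + cos 2y + cos 2z)
```

on a periodic grid (physical coordinates map to the dimensionless ones via
`x = 2πX/L`, with `L` the unit-cell edge). The skeletal solid is
`{f ≥ t}`; the package bisects the threshold `t` until the voxelized design
reaches a prescribed porosity (void volume fraction) `φ`, exports the
result as a watertight, print-ready STL mesh, and then closes the loop on
the *characterization* side: it renders the voxel model into binarized
axial slice stacks (the in-silico analogue of reconstructed micro-CT
images), and quantifies them the way an ImageJ workflow would —
ROI-restricted slice porosity and per-pore **Equivalent Circular Diameter**

```
ECD = 2 √(A / π)
```

via connected-component labeling with a minimum-size noise filter,
aggregated as mean ± SD and compared across geometries.

Intended users: tissue-engineering and biofabrication groups who design
TPMS scaffolds for 3D printing and validate them by micro-CT morphometry.

## Worked example

Design a 20%-porosity Gyroid scaffold on the Ø8 mm × 3 mm specimen
cylinder (2.5 mm unit cell, 40 µm voxel pitch), export the mesh, image it
and measure it:

```r
library(tpmscaffold)

d <- scaffold_design("gyroid", target_porosity = 0.2,
                     domain = domain_cylinder(8, 3), pitch = 40)
d
#> <calibration: gyroid skeletal, t = -0.91399 -> porosity 0.1997 (target 0.2) in 7 iterations>

mesh <- extract_surface(d)
is_watertight(mesh)          #> TRUE
mesh_volume(mesh)            #> 120.7 mm^3  (≈ 0.8 × the cylinder volume)
write_stl(mesh, stl_filename("gyroid", 0.2, 2.5))

stack <- render_slices(d$model)
stack
#> <slice_stack: 75 slices of 200 x 200 px, 40 um/px, axis z>

ps <- pore_stats(stack, roi = roi_circle(), min_size_px = 4)
glance(ps)
#> # A tibble: 1 × 6
#>   n_slices mean_porosity sd_porosity n_pores mean_ecd_um sd_ecd_um
#> 1       75         0.200     0.00764     784       1032.      397.
```

The calibration realizes the design porosity to 0.1997 (bisection
tolerance 1e-3); the 75 axial slices measure back a mean in-ROI porosity
of 0.200, and the 784 labeled pore openings average 1032 µm in ECD.

Comparing the three geometries at matched cell size and matched porosity:

```r
res <- pipeline_compare(tpms_geometries(), target_porosity = 0.2, pitch = 50)
writeLines(format_comparison(res$comparison))
#> Scaffold architecture comparison (ranked by mean ECD)
#> geometry   porosity (mean+/-SD)     ECD um (mean+/-SD)  n_pores  rank
#> gyroid        0.2006 +/- 0.0079       1050.4 +/-  391.6      613    1
#> diamond       0.1997 +/- 0.0253        848.0 +/-  357.1      906    2
#> iwp           0.2004 +/- 0.1362        683.3 +/-  753.8      744    3
```

At identical porosity the Gyroid presents the largest pore openings and
the I-WP the smallest — pore size is a property of the architecture, not
only of the porosity setting.

A thin command-line wrapper over the same functions ships in
`inst/scripts/tpmscaffold.R` (subcommands `generate`, `slices`, `analyze`,
`pipeline`; exit codes 0/2/3/4 for success/validation/convergence/I-O).

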