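#' Run manifest for provenance
#'
#' Collects every resolved parameter of a pipeline stage into one record so
#' a run can be reproduced exactly (same platform floating point assumed).
#'
#' @param design A `scaffold_design`.
#' @param ... Further resolved parameters to record (e.g. imaging and
#'   morphometry settings).
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(design, ...) {
  cal <- design$calibration
  dom <- cal$domain
  structure(
    c(list(
      geometry = cal$geometry,
      cell_mm = cal$cell,
      domain_shape = dom$shape,
      domain_dimensions_mm = if (dom$shape == "cylinder")
        c(diameter = dom$diameter, height = dom$height)
      else c(lx = dom$lx, ly = dom$ly, lz = dom$lz),
      mode = cal$mode,
      target_porosity = cal$target,
      calibrated_threshold = cal$threshold,
      realized_porosity = cal$realized,
      calibration_tolerance = cal$tol,
      calibration_iterations = cal$iterations,
      pitch_um = cal$pitch,
      units = "mm (mesh), um (pitch, pixel size)",
      package_version = as.character(utils::packageVersion("tpmscaffold")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ), list(...)),
    class = "run_manifest"
  )
}

#' @param manifest A `run_manifest`.
#' @param path JSON output path.
#' @rdname run_manifest
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Design-to-report scaffold pipeline
#'
#' The staged end-to-end workflow for one geometry: calibrate the level-set
#' threshold to the target porosity, voxelize, extract and (optionally)
#' write the print-ready STL mesh, render the axial slice stack, optionally
#' degrade it, and run the full morphometry.  With `out_dir` set, the STL,
#' TIFF stack + sidecar, CSV tables and the run manifest are written there.
#'
#' @inheritParams scaffold_design
#' @inheritParams pore_stats
#' @param blur_sigma_px Gaussian degradation sigma in pixels (0 = pristine).
#' @param seed Seed forwarded to [degrade()].
#' @param write_mesh Extract and export the STL surface (default `TRUE`;
#'   skip for imaging-only studies).
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @return A list: `design`, `mesh` (or `NULL`), `stack`, `stats`,
#'   `manifest`.
#' @export
scaffold_pipeline <- function(geometry, target_porosity = 0.2,
                              domain = domain_cylinder(), cell = 2.5,
                              pitch = 40, mode = c("skeletal", "sheet"),
                              roi = roi_circle(), connectivity = 8,
                              min_size_px = 4, include_boundary = TRUE,
                              blur_sigma_px = 0, seed = 0,
                              write_mesh = TRUE, out_dir = NULL,
                              verbose = FALSE) {
  mode <- match.arg(mode)
  design <- scaffold_design(geometry, target_porosity = target_porosity,
                            domain = domain, cell = cell, pitch = pitch,
                            mode = mode, verbose = verbose)
  mesh <- if (write_mesh) extract_surface(design) else NULL
  stack <- render_slices(design$model, axis = "z")
  if (blur_sigma_px > 0) {
    stack <- degrade(stack, blur_sigma_px = blur_sigma_px, seed = seed)
  }
  stats <- pore_stats(stack, roi = roi, connectivity = connectivity,
                      min_size_px = min_size_px,
                      include_boundary = include_boundary)
  manifest <- run_manifest(design,
                           slice_axis = "z",
                           blur_sigma_px = blur_sigma_px,
                           seed = seed,
                           roi_shape = roi$shape,
                           connectivity = connectivity,
                           min_size_px = min_size_px,
                           include_boundary = include_boundary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(mesh)) {
      write_stl(mesh, file.path(out_dir,
                                stl_filename(geometry, target_porosity, cell)))
    }
    write_stack(stack, file.path(out_dir, sprintf("%s_stack.tiff", geometry)))
    write_morphometry_csv(stats, out_dir)
    write_run_manifest(manifest, file.path(out_dir, "manifest.json"))
  }
  list(design = design, mesh = mesh, stack = stack, stats = stats,
       manifest = manifest)
}

#' Matched-design comparison across geometries
#'
#' Runs the pipeline for several geometries at identical cell size, domain
#' and target porosity, then ranks their pore architecture with
#' [compare_geometries()].  This is the in-silico analogue of scanning a
#' matched scaffold series.
#'
#' @inheritParams scaffold_pipeline
#' @param geometries Character vector of geometries to compare.
#' @return A list: `runs` (per-geometry pipeline results), `comparison`
#'   (ranked tibble).
#' @export
pipeline_compare <- function(geometries = tpms_geometries(),
                             target_porosity = 0.2,
                             domain = domain_cylinder(), cell = 2.5,
                             pitch = 40, min_size_px = 4, out_dir = NULL,
                             ...) {
  runs <- lapply(geometries, function(g) {
    scaffold_pipeline(g, target_porosity = target_porosity, domain = domain,
                      cell = cell, pitch = pitch, min_size_px = min_size_px,
                      write_mesh = FALSE,
                      out_dir = if (is.null(out_dir)) NULL
                                else file.path(out_dir, g), ...)
  })
  names(runs) <- geometries
  comparison <- compare_geometries(lapply(runs, `[[`, "stats"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    writeLines(format_comparison(comparison),
               file.path(out_dir, "comparison.txt"))
  }
  list(runs = runs, comparison = comparison)
}
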