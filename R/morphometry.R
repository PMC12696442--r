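#' Regions of interest for slice morphometry
#'
#' Measurements are restricted to a fixed ROI applied identically to every
#' slice, mirroring scanner-software practice.  `roi_full()` measures the
#' whole image, `roi_circle()` a disc (by default the largest disc inscribed
#' in the image, which coincides with the specimen boundary for a cylinder
#' scanned to fit), `roi_rect()` a pixel-aligned rectangle.
#'
#' @param center_px Disc centre `(row, col)` in pixels; image centre if `NULL`.
#' @param radius_px Disc radius in pixels; inscribed radius if `NULL`.
#' @return An `roi_spec` object.
#' @export
roi_circle <- function(center_px = NULL, radius_px = NULL) {
  structure(list(shape = "circle", center_px = center_px,
                 radius_px = radius_px), class = "roi_spec")
}

#' @param rows,cols Integer ranges `c(min, max)` of the rectangle, in pixels.
#' @rdname roi_circle
#' @export
roi_rect <- function(rows, cols) {
  stopifnot(length(rows) == 2L, length(cols) == 2L,
            rows[1] >= 1, cols[1] >= 1, rows[2] >= rows[1], cols[2] >= cols[1])
  structure(list(shape = "rectangle", rows = as.integer(rows),
                 cols = as.integer(cols)), class = "roi_spec")
}

#' @rdname roi_circle
#' @export
roi_full <- function() structure(list(shape = "full"), class = "roi_spec")

#' @export
print.roi_spec <- function(x, ...) {
  cat("<roi:", x$shape, "(", switch(x$shape,
    full = "whole image",
    circle = if (is.null(x$radius_px)) "inscribed disc"
             else sprintf("r = %g px", x$radius_px),
    rectangle = sprintf("rows %d..%d, cols %d..%d",
                        x$rows[1], x$rows[2], x$cols[1], x$cols[2])),
    ")>\n")
  invisible(x)
}

roi_mask <- function(roi, dims) {
  stopifnot(inherits(roi, "roi_spec"), length(dims) >= 2L)
  nr <- dims[1]; nc <- dims[2]
  m <- switch(roi$shape,
    full = matrix(TRUE, nr, nc),
    rectangle = {
      if (roi$rows[2] > nr || roi$cols[2] > nc) {
        stop("ROI rectangle exceeds the image bounds", call. = FALSE)
      }
      m <- matrix(FALSE, nr, nc)
      m[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]] <- TRUE
      m
    },
    circle = {
      cen <- roi$center_px %||% c((nr + 1) / 2, (nc + 1) / 2)
      rad <- roi$radius_px %||% (min(nr, nc) / 2)
      if (rad <= 0) stop("ROI radius must be positive", call. = FALSE)
      outer(seq_len(nr), seq_len(nc),
            function(r, c) (r - cen[1])^2 + (c - cen[2])^2 <= rad^2)
    }
  )
  if (!any(m)) stop("empty ROI", call. = FALSE)
  m
}

#' Porosity of one binarized slice inside an ROI
#'
#' The pore area fraction: pore pixels divided by the total measured
#' cross-section.  The measured region is the ROI intersected with the
#' printable domain, so exterior background (`NA` pixels) is never counted
#' on either side of the ratio.
#'
#' @param slice Integer matrix with values 1 (solid), 0 (pore), `NA`
#'   (outside domain).
#' @param roi An [roi_circle()]/[roi_rect()]/[roi_full()] spec.
#' @return Porosity in `[0, 1]`.
#' @export
slice_porosity <- function(slice, roi = roi_full()) {
  stopifnot(is.matrix(slice))
  region <- roi_mask(roi, dim(slice)) & !is.na(slice)
  n <- sum(region)
  if (n == 0L) stop("ROI does not intersect the imaged domain", call. = FALSE)
  sum(slice[region] == 0L) / n
}

#' Label pores in one slice and measure their ECD
#'
#' Connected components of the pore phase inside the ROI, with a minimum
#' pixel-area threshold discarding noise specks, the way a particle-analysis
#' workflow does.  Each surviving pore gets its pixel area, physical area,
#' Equivalent Circular Diameter `ECD = 2 sqrt(A / pi)` and centroid;
#' components touching the boundary of the measured region are flagged (they
#' are truncated, so their ECD underestimates the true pore).
#'
#' @inheritParams slice_porosity
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param min_size_px Minimum component area in pixels (default 4).
#' @param pixel_size Pixel size in micrometres.
#' @return A tibble with one row per pore: `label`, `area_px`, `area_um2`,
#'   `ecd_um`, `centroid_row`, `centroid_col`, `touches_boundary`.
#' @export
label_pores <- function(slice, roi = roi_full(), connectivity = 8,
                        min_size_px = 4, pixel_size = 1) {
  stopifnot(is.matrix(slice), connectivity %in% c(4, 8), min_size_px >= 1,
            pixel_size > 0)
  region <- roi_mask(roi, dim(slice)) & !is.na(slice)
  pore <- matrix(0L, nrow(slice), ncol(slice))
  pore[region & !is.na(slice) & slice == 0L] <- 1L
  lab <- cpp_label_components(pore, as.integer(connectivity))
  nlab <- max(lab)
  if (nlab == 0L) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          area_um2 = numeric(), ecd_um = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          touches_boundary = logical()))
  }
  areas <- tabulate(lab, nbins = nlab)

  # boundary of the measured region: region pixels with a 4-neighbour outside it
  pad <- rbind(FALSE, cbind(FALSE, region, FALSE), FALSE)
  nr <- nrow(region); nc <- ncol(region)
  interior <- pad[2:(nr + 1), 2:(nc + 1)] &
    pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  boundary_labels <- unique(lab[region & !interior & lab > 0L])

  idx <- which(lab > 0L)
  ll <- lab[idx]
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  keep <- which(areas >= min_size_px)
  tibble::tibble(
    label = keep,
    area_px = areas[keep],
    area_um2 = areas[keep] * pixel_size^2,
    ecd_um = 2 * sqrt(areas[keep] * pixel_size^2 / pi),
    centroid_row = vapply(keep, function(l) mean(rr[ll == l]), numeric(1)),
    centroid_col = vapply(keep, function(l) mean(cc[ll == l]), numeric(1)),
    touches_boundary = keep %in% boundary_labels
  )
}

#' Morphometry of a whole slice stack
#'
#' Applies [slice_porosity()] and [label_pores()] to every slice of a stack
#' and aggregates: per-slice porosity, the pooled pore table, and mean +/-
#' sample standard deviation (n - 1) of porosity over slices and of ECD over
#' pores.  With fewer than two observations the SD is `NA`; with zero pores
#' the ECD summary is `NA` and `n_pores` is 0 rather than an error.
#'
#' @param stack A `slice_stack`.
#' @inheritParams label_pores
#' @param include_boundary Include pores touching the ROI/domain boundary in
#'   the ECD aggregates (default `TRUE`; they remain flagged in the records).
#' @return A `pore_stats` object; see [tidy.pore_stats()] and
#'   [glance.pore_stats()] for tabular access.
#' @export
pore_stats <- function(stack, roi = roi_full(), connectivity = 8,
                       min_size_px = 4, include_boundary = TRUE) {
  stopifnot(inherits(stack, "slice_stack"))
  ns <- n_slices(stack)
  per_slice <- numeric(ns)
  pores <- vector("list", ns)
  for (k in seq_len(ns)) {
    sl <- stack$data[, , k]
    per_slice[k] <- slice_porosity(sl, roi)
    p <- label_pores(sl, roi, connectivity = connectivity,
                     min_size_px = min_size_px,
                     pixel_size = stack$pixel_size)
    if (nrow(p)) p <- dplyr::mutate(p, slice = k, .before = 1)
    pores[[k]] <- p
  }
  pores <- dplyr::bind_rows(pores)
  ecd <- if (include_boundary || nrow(pores) == 0L) pores$ecd_um
         else pores$ecd_um[!pores$touches_boundary]
  summary <- tibble::tibble(
    n_slices = ns,
    mean_porosity = mean(per_slice),
    sd_porosity = if (ns >= 2L) stats::sd(per_slice) else NA_real_,
    n_pores = length(ecd),
    mean_ecd_um = if (length(ecd)) mean(ecd) else NA_real_,
    sd_ecd_um = if (length(ecd) >= 2L) stats::sd(ecd) else NA_real_
  )
  structure(
    list(slices = tibble::tibble(slice = seq_len(ns), porosity = per_slice),
         pores = pores, summary = summary,
         pixel_size = stack$pixel_size,
         params = list(connectivity = connectivity, min_size_px = min_size_px,
                       include_boundary = include_boundary)),
    class = "pore_stats"
  )
}

#' @export
print.pore_stats <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pore_stats: %d slices, porosity %.4f +/- %s; %d pores, ECD %s +/- %s um>\n",
    s$n_slices, s$mean_porosity, format(signif(s$sd_porosity, 3)),
    s$n_pores, format(signif(s$mean_ecd_um, 5)), format(signif(s$sd_ecd_um, 3))))
  invisible(x)
}

#' Tidy pore statistics
#'
#' @param x A `pore_stats` object.
#' @param type `"pores"` (one row per pore, the default) or `"slices"`
#'   (one row per slice with its porosity).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pore_stats <- function(x, type = c("pores", "slices"), ...) {
  switch(match.arg(type), pores = x$pores, slices = x$slices)
}

#' @rdname tidy.pore_stats
#' @return `glance()`: the one-row aggregate summary.
#' @export
glance.pore_stats <- function(x, ...) x$summary

#' Compare morphometry across scaffold geometries
#'
#' Assembles the aggregate summaries of several `pore_stats` objects into a
#' ranked table (rank 1 = largest mean ECD), with an explicit tie flag.
#' All stacks must share one pixel size, otherwise the ECDs are not
#' commensurable.
#'
#' @param stats A named list of `pore_stats` (names identify the
#'   geometries); every entry must have at least one pore.
#' @return A tibble: geometry, porosity and ECD aggregates, `ecd_rank`, and
#'   `tied` flag.
#' @export
compare_geometries <- function(stats) {
  stopifnot(is.list(stats), length(stats) >= 2L,
            all(vapply(stats, inherits, logical(1), "pore_stats")))
  if (is.null(names(stats)) || any(!nzchar(names(stats)))) {
    stop("`stats` must be a named list (names identify the geometries)",
         call. = FALSE)
  }
  px <- vapply(stats, function(s) s$pixel_size, numeric(1))
  if (length(unique(px)) != 1L) {
    stop("pixel sizes differ across stacks (",
         paste(unique(px), collapse = ", "),
         " um); ECDs are not comparable", call. = FALSE)
  }
  if (any(vapply(stats, function(s) s$summary$n_pores, integer(1)) == 0L)) {
    stop("every pore_stats entry must contain at least one pore", call. = FALSE)
  }
  tbl <- dplyr::bind_rows(lapply(stats, function(s) s$summary), .id = "geometry")
  tbl$ecd_rank <- rank(-tbl$mean_ecd_um, ties.method = "min")
  tbl$tied <- duplicated(tbl$mean_ecd_um) | duplicated(tbl$mean_ecd_um, fromLast = TRUE)
  dplyr::arrange(tbl, .data$ecd_rank)
}

#' Write morphometry outputs as CSV
#'
#' Emits the three conventional tables into a directory: `pores.csv` (one
#' pore per row), `slices.csv` (per-slice porosity) and `summary.csv`
#' (the aggregates; one row per geometry when given a comparison table).
#'
#' @param x A `pore_stats` object or a [compare_geometries()] tibble.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_morphometry_csv <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "pore_stats")) {
    utils::write.csv(x$pores, file.path(dir, "pores.csv"), row.names = FALSE)
    utils::write.csv(x$slices, file.path(dir, "slices.csv"), row.names = FALSE)
    utils::write.csv(x$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  } else {
    utils::write.csv(x, file.path(dir, "summary.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Human-readable comparison report
#'
#' @param comparison A [compare_geometries()] tibble.
#' @return Character vector of report lines.
#' @export
format_comparison <- function(comparison) {
  c("Scaffold architecture comparison (ranked by mean ECD)",
    sprintf("%-10s %18s %22s %8s %5s", "geometry", "porosity (mean+/-SD)",
            "ECD um (mean+/-SD)", "n_pores", "rank"),
    sprintf("%-10s %9.4f +/- %6.4f %12.1f +/- %6.1f %8d %4d%s",
            comparison$geometry, comparison$mean_porosity,
            comparison$sd_porosity, comparison$mean_ecd_um,
            comparison$sd_ecd_um, comparison$n_pores, comparison$ecd_rank,
            ifelse(comparison$tied, " (tie)", "")))
}
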