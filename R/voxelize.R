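#' Sample a TPMS field over a printable domain
#'
#' Evaluates the nodal equation of `geometry` at every voxel centre of an
#' isotropic grid covering the domain's bounding box.  Physical coordinates X
#' (mm) map to the dimensionless equation coordinates as `x = 2*pi*X / cell`,
#' so `cell` is the edge length of one cubic period.  The grid is centred on
#' the origin, matching the domain conventions of [domain_cylinder()].
#'
#' @param geometry One of [tpms_geometries()].
#' @param domain A [domain_cylinder()] or [domain_box()] object.
#' @param pitch Isotropic voxel pitch in micrometres.
#' @param cell Unit-cell edge length L in mm (default 2.5).
#' @param max_voxels Voxel budget; grids larger than this are rejected with a
#'   suggestion to coarsen the pitch.
#' @return A `field_grid` object: the sampled `values` array, the logical
#'   in-domain `mask`, the voxel-centre `axes` (mm), and the design metadata.
#' @export
#' @examples
#' fg <- field_on_grid("gyroid", domain_box(2.5, 2.5, 2.5), pitch = 100)
#' dim(fg$values)
field_on_grid <- function(geometry, domain = domain_cylinder(), pitch = 40,
                          cell = 2.5, max_voxels = 2e8) {
  geometry <- match_geometry(geometry)
  stopifnot(inherits(domain, "domain_spec"),
            is.numeric(cell), length(cell) == 1L, cell > 0)
  axes <- domain_axes(domain, pitch)
  n <- lengths(axes)
  if (prod(n) > max_voxels) {
    stop("grid of ", paste(n, collapse = " x "), " = ", prod(n),
         " voxels exceeds the budget of ", max_voxels,
         "; coarsen the pitch (try ", signif(pitch * (prod(n) / max_voxels)^(1 / 3), 3),
         " um) or raise max_voxels", call. = FALSE)
  }
  k <- 2 * pi / cell
  Xm <- matrix(axes[[1]], n[1], n[2])
  Ym <- matrix(axes[[2]], n[1], n[2], byrow = TRUE)
  values <- array(NA_real_, dim = n)
  for (iz in seq_len(n[3])) {
    values[, , iz] <- nodal_value(geometry, k * Xm, k * Ym, k * axes[[3]][iz])
  }
  mask <- array(TRUE, dim = n)
  if (domain$shape == "cylinder") {
    r2 <- (domain$diameter / 2)^2
    mask[] <- c(Xm^2 + Ym^2 <= r2)  # recycled along z
  }
  structure(
    list(values = values, mask = mask, axes = axes, pitch = pitch,
         geometry = geometry, cell = cell, domain = domain),
    class = "field_grid"
  )
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid: %s, %s voxels, pitch %g um, cell %g mm>\n",
              x$geometry, paste(dim(x$values), collapse = " x "),
              x$pitch, x$cell))
  invisible(x)
}

#' Threshold a sampled field into a solid/void voxel model
#'
#' Applies a level-set rule to the scalar field: in `skeletal` mode the solid
#' is one labyrinth of the surface, `{f >= t}`, so raising the threshold
#' raises the porosity; in `sheet` mode the solid is a shell of half-thickness
#' t around the surface, `{|f| <= t}` with `t >= 0`.  Occupancy is always
#' intersected with the domain mask.
#'
#' @param field A `field_grid` from [field_on_grid()].
#' @param threshold Level-set threshold t.
#' @param mode `"skeletal"` (default) or `"sheet"`.
#' @return A `voxel_model`: binary occupancy and domain mask on the grid,
#'   with physical pitch and origin.
#' @export
solidify <- function(field, threshold = 0, mode = c("skeletal", "sheet")) {
  stopifnot(inherits(field, "field_grid"),
            is.numeric(threshold), length(threshold) == 1L, is.finite(threshold))
  mode <- match.arg(mode)
  if (mode == "sheet" && threshold < 0) {
    stop("sheet mode requires a nonnegative threshold", call. = FALSE)
  }
  occ <- if (mode == "skeletal") field$values >= threshold
         else abs(field$values) <= threshold
  occ <- occ & field$mask
  structure(
    list(occupancy = occ, mask = field$mask,
         pitch = field$pitch,
         origin = vapply(field$axes, `[`, numeric(1), 1L),
         geometry = field$geometry, cell = field$cell,
         domain = field$domain, mode = mode, threshold = threshold),
    class = "voxel_model"
  )
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf(
    "<voxel_model: %s %s, t = %.6g, %s voxels, pitch %g um, porosity %.4f>\n",
    x$geometry, x$mode, x$threshold, paste(dim(x$occupancy), collapse = " x "),
    x$pitch, void_fraction(x)))
  invisible(x)
}

#' Void (pore) volume fraction of a voxel model
#'
#' Porosity is the fraction of in-domain voxels that are not solid:
#' `1 - solid voxels / domain voxels`.  Voxels outside the domain mask are
#' ignored entirely.
#'
#' @param x A `voxel_model`.
#' @param ... Unused.
#' @return A number in `[0, 1]`.
#' @export
void_fraction <- function(x, ...) UseMethod("void_fraction")

#' @export
void_fraction.voxel_model <- function(x, ...) {
  nd <- sum(x$mask)
  if (nd == 0L) stop("degenerate domain: the domain mask is empty", call. = FALSE)
  1 - sum(x$occupancy) / nd
}
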