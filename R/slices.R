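#' Binary slice stacks
#'
#' The in-silico stand-in for reconstructed micro-CT output: an ordered stack
#' of binarized axial images on a uniform grid.  Slices are stored as an
#' integer array `[row, col, slice]` with three levels: `1` solid, `0` pore,
#' and `NA` for pixels outside the printable domain.  Keeping the exterior
#' distinct from in-domain pore mirrors the role of the consistent ROI in a
#' scanner workflow: background must never inflate porosity.
#'
#' @param data Integer array `[nr, nc, nslices]` with values 1/0/NA.
#' @param pixel_size In-plane pixel size in micrometres.
#' @param slice_spacing Distance between slices in micrometres.
#' @param axis Which axis was sliced (`"x"`, `"y"` or `"z"`).
#' @param truth Optional ground-truth record (phantoms only).
#' @return A `slice_stack` object.
#' @export
slice_stack <- function(data, pixel_size, slice_spacing = pixel_size,
                        axis = "z", truth = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            is.numeric(pixel_size), pixel_size > 0, slice_spacing > 0,
            axis %in% c("x", "y", "z"))
  storage.mode(data) <- "integer"
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0L, 1L, NA_integer_))) {
    stop("slice data must be 1 (solid), 0 (pore) or NA (outside domain)",
         call. = FALSE)
  }
  structure(
    list(data = data, pixel_size = pixel_size, slice_spacing = slice_spacing,
         axis = axis, truth = truth),
    class = "slice_stack"
  )
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<slice_stack: %d slices of %d x %d px, %.4g um/px, axis %s%s>\n",
              d[3], d[1], d[2], x$pixel_size, x$axis,
              if (!is.null(x$truth)) ", with ground truth" else ""))
  invisible(x)
}

n_slices <- function(stack) dim(stack$data)[3]

#' Render a voxel model into binarized slices
#'
#' Cuts the voxel model perpendicular to the chosen axis, one slice per voxel
#' layer, emulating the reconstructed axial image stack of a micro-CT scan at
#' the model's own resolution.  Pixel size and slice spacing both equal the
#' voxel pitch; voxels outside the domain mask become `NA` background.
#'
#' @param model A `voxel_model`.
#' @param axis Slicing axis; `"z"` (the cylinder axis, i.e. axial slices) by
#'   default.
#' @return A `slice_stack`.
#' @export
render_slices <- function(model, axis = c("z", "x", "y")) {
  stopifnot(inherits(model, "voxel_model"))
  axis <- match.arg(axis)
  occ <- model$occupancy
  msk <- model$mask
  perm <- switch(axis, z = c(1L, 2L, 3L), x = c(2L, 3L, 1L), y = c(1L, 3L, 2L))
  if (!identical(perm, c(1L, 2L, 3L))) {
    occ <- aperm(occ, perm)
    msk <- aperm(msk, perm)
  }
  dat <- array(NA_integer_, dim = dim(occ))
  dat[msk] <- 0L
  dat[occ] <- 1L
  slice_stack(dat, pixel_size = model$pitch, slice_spacing = model$pitch,
              axis = axis)
}

#' Degrade a slice stack the way reconstruction smoothing does
#'
#' Gaussian-blurs each binary slice and re-thresholds it, emulating the
#' smoothing applied during tomographic reconstruction; optionally flips a
#' random fraction of in-domain pixels first (speckle noise).  With
#' `blur_sigma_px = 0` and `noise = 0` the stack is returned unchanged.
#' Deterministic for a fixed `seed` (the seed only drives the speckle noise;
#' blurring itself is deterministic).
#'
#' @param stack A `slice_stack`.
#' @param blur_sigma_px Gaussian sigma in pixels (>= 0).
#' @param rebinarize_threshold Threshold in (0, 1) applied after blurring.
#' @param noise Fraction of in-domain pixels to flip before blurring.
#' @param seed Integer seed for the noise.
#' @return A degraded `slice_stack` with the same geometry metadata.
#' @export
degrade <- function(stack, blur_sigma_px, rebinarize_threshold = 0.5,
                    noise = 0, seed = 0) {
  stopifnot(inherits(stack, "slice_stack"),
            blur_sigma_px >= 0,
            rebinarize_threshold > 0, rebinarize_threshold < 1,
            noise >= 0, noise < 1)
  if (blur_sigma_px == 0 && noise == 0) return(stack)
  dat <- stack$data
  set.seed(as.integer(seed))
  for (k in seq_len(dim(dat)[3])) {
    sl <- dat[, , k]
    domain <- !is.na(sl)
    v <- sl
    v[!domain] <- 0L
    if (noise > 0) {
      idx <- which(domain)
      flip <- idx[stats::runif(length(idx)) < noise]
      v[flip] <- 1L - v[flip]
    }
    if (blur_sigma_px > 0) {
      b <- EBImage::gblur(matrix(as.numeric(v), nrow(v), ncol(v)),
                          sigma = blur_sigma_px)
      v <- matrix(as.integer(b >= rebinarize_threshold), nrow(v), ncol(v))
    }
    v[!domain] <- NA_integer_
    dat[, , k] <- v
  }
  slice_stack(dat, pixel_size = stack$pixel_size,
              slice_spacing = stack$slice_spacing, axis = stack$axis)
}

#' Analytic phantoms with known morphometry
#'
#' Builds binary stacks whose porosity and per-pore Equivalent Circular
#' Diameter are known by construction, for validating the morphometry
#' pipeline.  Three kinds are available: `single_pore` (one circular pore in
#' a solid field), `circular_channels` (n parallel circular channels, drawn
#' inside a solid disc when `disc_diameter_um` is given, otherwise inside a
#' solid rectangle), and `checkerboard` (alternating squares, porosity 1/2).
#'
#' The returned stack carries a `truth` record with the pixel-exact porosity
#' and per-pore ECD (in micrometres) plus the nominal analytic values.
#'
#' @param kind Phantom kind.
#' @param image_px Image size, `c(rows, cols)` in pixels.
#' @param pixel_size Pixel size in micrometres.
#' @param n_slices Number of identical slices.
#' @param diameter_um Pore/channel diameter in micrometres.
#' @param centers_px Optional `n x 2` matrix of channel centres (pixels,
#'   `(row, col)`); auto-laid-out on a ring when omitted.
#' @param n_channels Number of channels (when `centers_px` is omitted).
#' @param disc_diameter_um Diameter of the solid disc for
#'   `circular_channels`; `NULL` for a full rectangular solid.
#' @param square_px Checkerboard square edge in pixels.
#' @return A `slice_stack` with a `truth` record.
#' @export
make_phantom <- function(kind = c("single_pore", "circular_channels",
                                  "checkerboard"),
                         image_px = c(500L, 500L), pixel_size = 10,
                         n_slices = 1L, diameter_um = 500,
                         centers_px = NULL, n_channels = 4L,
                         disc_diameter_um = NULL, square_px = 8L) {
  kind <- match.arg(kind)
  stopifnot(length(image_px) == 2L, all(image_px >= 2), pixel_size > 0,
            n_slices >= 1L)
  nr <- as.integer(image_px[1]); nc <- as.integer(image_px[2])
  rc <- matrix(c(row(matrix(0, nr, nc)), col(matrix(0, nr, nc))), ncol = 2)

  if (kind == "checkerboard") {
    sq <- as.integer(square_px)
    stopifnot(sq >= 1L, nr %% (2L * sq) == 0L, nc %% (2L * sq) == 0L)
    board <- (((rc[, 1] - 1L) %/% sq) + ((rc[, 2] - 1L) %/% sq)) %% 2L
    sl <- matrix(as.integer(board == 0L), nr, nc)
    truth <- list(porosity = 0.5, porosity_nominal = 0.5,
                  ecd_um = numeric(0), n_pores = NA_integer_)
  } else {
    if (kind == "single_pore") {
      centers_px <- matrix(c((nr + 1) / 2, (nc + 1) / 2), 1, 2)
    } else if (is.null(centers_px)) {
      # equally spaced on a ring at half the available radius
      avail_r <- if (is.null(disc_diameter_um)) min(nr, nc) / 2
                 else disc_diameter_um / (2 * pixel_size)
      ang <- 2 * pi * (seq_len(n_channels) - 1) / n_channels
      centers_px <- cbind((nr + 1) / 2 + avail_r / 2 * sin(ang),
                          (nc + 1) / 2 + avail_r / 2 * cos(ang))
    }
    centers_px <- as.matrix(centers_px)
    r_px <- diameter_um / (2 * pixel_size)
    # feature validation: fit inside the image/disc, no overlaps
    if (nrow(centers_px) > 1L) {
      dd <- as.matrix(stats::dist(centers_px))
      if (any(dd[upper.tri(dd)] < 2 * r_px)) {
        stop("overlapping channels: centre spacing below one diameter",
             call. = FALSE)
      }
    }
    domain <- matrix(TRUE, nr, nc)
    if (!is.null(disc_diameter_um)) {
      disc_r <- disc_diameter_um / (2 * pixel_size)
      cen <- c((nr + 1) / 2, (nc + 1) / 2)
      domain <- matrix((rc[, 1] - cen[1])^2 + (rc[, 2] - cen[2])^2 <= disc_r^2,
                       nr, nc)
      lim <- disc_r - r_px
      off <- sqrt((centers_px[, 1] - cen[1])^2 + (centers_px[, 2] - cen[2])^2)
      if (any(off > lim)) stop("channels do not fit inside the disc", call. = FALSE)
    } else if (any(centers_px[, 1] < r_px + 1) || any(centers_px[, 1] > nr - r_px) ||
               any(centers_px[, 2] < r_px + 1) || any(centers_px[, 2] > nc - r_px)) {
      stop("channels do not fit inside the image", call. = FALSE)
    }
    sl <- matrix(1L, nr, nc)
    pore_areas <- integer(nrow(centers_px))
    for (i in seq_len(nrow(centers_px))) {
      hit <- (rc[, 1] - centers_px[i, 1])^2 + (rc[, 2] - centers_px[i, 2])^2 <= r_px^2
      pore_areas[i] <- sum(hit)
      sl[matrix(hit, nr, nc)] <- 0L
    }
    sl[!domain] <- NA_integer_
    truth <- list(
      porosity = sum(pore_areas) / sum(domain),
      porosity_nominal = nrow(centers_px) * pi * r_px^2 / sum(domain),
      ecd_um = 2 * sqrt(pore_areas / pi) * pixel_size,
      ecd_nominal_um = rep(diameter_um, nrow(centers_px)),
      n_pores = nrow(centers_px)
    )
  }
  dat <- array(rep(sl, n_slices), dim = c(nr, nc, n_slices))
  slice_stack(dat, pixel_size = pixel_size, truth = truth)
}

stack_sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write and read slice stacks as TIFF + JSON sidecar
#'
#' Stacks round-trip losslessly as multi-page 8-bit grayscale TIFF with the
#' three levels encoded as 1.0 (solid), 0.0 (pore) and 0.5 (outside domain),
#' plus a JSON sidecar carrying the physical metadata (pixel size, slice
#' spacing, axis).  `read_stack()` refuses stacks without a sidecar, naming
#' the required keys.
#'
#' @param stack A `slice_stack`.
#' @param path TIFF file path; the sidecar lives next to it as `.json`.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` the
#'   reconstructed `slice_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "slice_stack"))
  pages <- lapply(seq_len(n_slices(stack)), function(k) {
    sl <- stack$data[, , k]
    v <- matrix(0.5, nrow(sl), ncol(sl))
    v[!is.na(sl) & sl == 1L] <- 1
    v[!is.na(sl) & sl == 0L] <- 0
    v
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(pixel_size_um = stack$pixel_size,
               slice_spacing_um = stack$slice_spacing,
               axis = stack$axis, n_slices = n_slices(stack))
  jsonlite::write_json(meta, stack_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  side <- stack_sidecar_path(path)
  required <- c("pixel_size_um", "slice_spacing_um", "axis")
  if (!file.exists(side)) {
    stop("missing metadata sidecar ", side, "; required keys: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  missing_keys <- setdiff(required, names(meta))
  if (length(missing_keys)) {
    stop("metadata sidecar lacks required keys: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dat <- array(NA_integer_, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                                    length(pages)))
  for (k in seq_along(pages)) {
    v <- pages[[k]]
    sl <- matrix(NA_integer_, nrow(v), ncol(v))
    sl[v > 0.75] <- 1L
    sl[v < 0.25] <- 0L
    dat[, , k] <- sl
  }
  slice_stack(dat, pixel_size = meta$pixel_size_um,
              slice_spacing = meta$slice_spacing_um, axis = meta$axis)
}
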