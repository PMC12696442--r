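#' Triangle meshes
#'
#' Minimal container for a triangle surface mesh: an `n x 3` matrix of vertex
#' coordinates in mm and an `m x 3` integer matrix of 1-based vertex indices
#' per face.  Faces are wound counter-clockwise seen from outside, so the
#' signed volume of a closed mesh is positive.
#'
#' @param vertices Numeric matrix, one row per vertex (mm).
#' @param faces Integer matrix, one row per triangle.
#' @return A `triangle_mesh` object.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3 || nrow(vertices) == 0,
            ncol(faces) == 3 || nrow(faces) == 0)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Extract a capped isosurface mesh from a scaffold design
#'
#' Runs marching tetrahedra on the level-set field of the solid, after
#' min-combining it with the signed distance to the domain boundary.  The
#' combination makes the domain walls (cylinder barrel and end faces, or box
#' faces) part of the zero level set, so the extracted surface is closed in a
#' single pass; a negative padding layer outside the grid guarantees the mesh
#' never ends at the sampling boundary.
#'
#' @param x A `scaffold_design` (threshold taken from its calibration) or a
#'   `field_grid`.
#' @param ... Passed to methods.
#' @return A watertight `triangle_mesh` in physical mm coordinates.
#' @export
extract_surface <- function(x, ...) UseMethod("extract_surface")

#' @export
extract_surface.scaffold_design <- function(x, ...) {
  extract_surface(x$field, threshold = x$calibration$threshold,
                  mode = x$calibration$mode, ...)
}

#' @param threshold Level-set threshold t (already calibrated).
#' @param mode `"skeletal"` or `"sheet"`.
#' @rdname extract_surface
#' @export
extract_surface.field_grid <- function(x, threshold = 0,
                                       mode = c("skeletal", "sheet"), ...) {
  mode <- match.arg(mode)
  n <- dim(x$values)
  if (any(n < 2L)) stop("grid must have at least 2 voxels per axis", call. = FALSE)
  h <- x$pitch / 1000  # mm

  # solid indicator field, positive inside the solid
  s <- if (mode == "skeletal") x$values - threshold else threshold - abs(x$values)
  if (!any(s >= 0)) stop("no surface at this threshold: the solid is empty",
                         call. = FALSE)

  # min-combine with the signed domain distance on a grid padded by one
  # voxel layer: the padding lies outside the domain, where the distance is
  # negative, so the isosurface closes exactly on the domain walls
  np <- n + 2L
  paxes <- lapply(x$axes, function(a) c(a[1] - h, a, a[length(a)] + h))
  Xm <- matrix(paxes[[1]], np[1], np[2])
  Ym <- matrix(paxes[[2]], np[1], np[2], byrow = TRUE)
  sp <- array(NA_real_, dim = np)
  for (iz in seq_len(np[3])) {
    d <- domain_signed_distance(x$domain, Xm, Ym, paxes[[3]][iz])
    sl <- d
    if (iz > 1L && iz < np[3]) {
      sl[2:(np[1] - 1L), 2:(np[2] - 1L)] <-
        pmin(s[, , iz - 1L], d[2:(np[1] - 1L), 2:(np[2] - 1L)])
    }
    sp[, , iz] <- sl
  }
  origin <- vapply(paxes, `[`, numeric(1), 1L)

  res <- cpp_marching_tetrahedra(as.numeric(sp), np, h, origin)
  triangle_mesh(res$vertices, res$faces)
}

#' Watertightness of a triangle mesh
#'
#' A mesh is watertight when every edge is shared by exactly two faces.
#'
#' @param mesh A `triangle_mesh`.
#' @return `open_edge_count()`: number of defective edges; `is_watertight()`:
#'   `TRUE` when that count is zero.
#' @export
open_edge_count <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$faces) == 0L) return(0L)
  cpp_open_edge_count(mesh$faces)
}

#' @rdname open_edge_count
#' @export
is_watertight <- function(mesh) open_edge_count(mesh) == 0L

#' Signed volume of a watertight mesh
#'
#' Divergence-theorem volume as the sum of signed origin-tetrahedra over all
#' faces; positive for consistently outward-oriented meshes.  Serves as the
#' independent cross-check of voxel-counted scaffold volume.
#'
#' @param mesh A watertight `triangle_mesh`.
#' @return Volume in mm^3 (negative if the orientation is inverted).
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  open <- open_edge_count(mesh)
  if (open > 0L) {
    stop("mesh is not watertight: ", open,
         " edges are not shared by exactly two faces", call. = FALSE)
  }
  cpp_mesh_volume(mesh$vertices, mesh$faces)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Write and read STL files
#'
#' Binary STL (80-byte header, little-endian uint32 triangle count, 50 bytes
#' per triangle) is the default dialect; ASCII STL is available for
#' inspection.  Coordinates are written in mm, unlabeled per STL convention.
#' Binary STL stores float32, so coordinates not exactly representable in
#' single precision are quantized on write.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output file path.
#' @param format `"binary"` (default) or `"ascii"`.
#' @return `write_stl()` returns `path` invisibly; `read_stl()` returns a
#'   `triangle_mesh` with exact duplicate vertices merged.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  nf <- nrow(mesh$faces)
  if (nf >= 2^32) stop("triangle count overflows the STL uint32 field", call. = FALSE)
  if (format == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "tpmscaffold binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    if (nf > 0L) {
      nrm <- face_normals(mesh)
      v <- mesh$vertices
      f <- mesh$faces
      dat <- cbind(nrm, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE])           # nf x 12
      fr <- writeBin(as.numeric(t(dat)), raw(), size = 4, endian = "little")
      dim(fr) <- c(48L, nf)
      buf <- rbind(fr, matrix(as.raw(0), 2L, nf))       # 2-byte attribute
      writeBin(as.raw(buf), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid tpmscaffold", con)
    if (nf > 0L) {
      nrm <- face_normals(mesh)
      v <- mesh$vertices
      f <- mesh$faces
      lines <- character(nf * 7L)
      for (i in seq_len(nf)) {
        tri <- v[f[i, ], , drop = FALSE]
        lines[(i - 1L) * 7L + 1:7] <- c(
          sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
          "    outer loop",
          sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
          "    endloop",
          "  endfacet")
      }
      writeLines(lines, con)
    }
    writeLines("endsolid tpmscaffold", con)
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  size <- file.info(path)$size
  if (is.na(size)) stop("cannot read ", path, call. = FALSE)
  is_binary <- FALSE
  if (size >= 84) {
    con <- file(path, "rb")
    seek(con, 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    close(con)
    if (!is.na(nf) && nf >= 0 && size == 84 + 50 * as.numeric(nf)) is_binary <- TRUE
  }
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    seek(con, 80)
    nf <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (nf == 0L) return(triangle_mesh(matrix(numeric(0), 0, 3),
                                       matrix(integer(0), 0, 3)))
    buf <- readBin(con, "raw", 50 * nf)
    dim(buf) <- c(50L, nf)
    vals <- readBin(as.raw(buf[1:48, ]), "numeric", 12L * nf, size = 4,
                    endian = "little")
    dat <- matrix(vals, ncol = 12L, byrow = TRUE)
    soup <- matrix(t(dat[, 4:12, drop = FALSE]), ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) %% 3 != 0) stop("malformed ASCII STL: vertex count not a multiple of 3",
                                   call. = FALSE)
    soup <- matrix(as.numeric(unlist(strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)),
                                              "\\s+"))), ncol = 3, byrow = TRUE)
  }
  # merge exactly identical vertices, keeping first-appearance order
  key <- paste(soup[, 1], soup[, 2], soup[, 3])
  idx <- match(key, unique(key))
  verts <- soup[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces)
}

#' Conventional STL file name for a scaffold design
#'
#' @param geometry,porosity,cell Design parameters.
#' @return `"{geometry}_{porosity}_{cell}mm.stl"`.
#' @export
stl_filename <- function(geometry, porosity, cell) {
  sprintf("%s_%s_%smm.stl", match_geometry(geometry),
          format(porosity), format(cell))
}
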