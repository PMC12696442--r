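#' Printable scaffold domains
#'
#' A domain describes the physical envelope a scaffold is generated inside:
#' either a cylinder (the compression-specimen preset, Ø8 mm x 3 mm, is the
#' default throughout the package) or an axis-aligned box.  All dimensions are
#' in millimetres; the domain is centred on the origin with the cylinder axis
#' along z.
#'
#' @param diameter,height Cylinder dimensions in mm.
#' @return A `domain_spec` object.
#' @export
#' @examples
#' domain_cylinder()          # the 8 x 3 mm specimen
#' domain_box(2.5, 2.5, 2.5)  # one default unit cell
domain_cylinder <- function(diameter = 8, height = 3) {
  stopifnot(is.numeric(diameter), length(diameter) == 1L, diameter > 0,
            is.numeric(height), length(height) == 1L, height > 0)
  structure(
    list(shape = "cylinder", diameter = diameter, height = height),
    class = "domain_spec"
  )
}

#' @param lx,ly,lz Box edge lengths in mm.
#' @rdname domain_cylinder
#' @export
domain_box <- function(lx, ly, lz = lx) {
  stopifnot(is.numeric(lx), lx > 0, is.numeric(ly), ly > 0,
            is.numeric(lz), lz > 0)
  structure(
    list(shape = "box", lx = lx, ly = ly, lz = lz),
    class = "domain_spec"
  )
}

#' @export
print.domain_spec <- function(x, ...) {
  if (x$shape == "cylinder") {
    cat(sprintf("<domain: cylinder Ø%g mm x %g mm>\n", x$diameter, x$height))
  } else {
    cat(sprintf("<domain: box %g x %g x %g mm>\n", x$lx, x$ly, x$lz))
  }
  invisible(x)
}

domain_extent <- function(domain) {
  switch(domain$shape,
    cylinder = c(domain$diameter, domain$diameter, domain$height),
    box      = c(domain$lx, domain$ly, domain$lz)
  )
}

domain_volume <- function(domain) {
  switch(domain$shape,
    cylinder = pi * (domain$diameter / 2)^2 * domain$height,
    box      = domain$lx * domain$ly * domain$lz
  )
}

# Voxel-centre coordinate vectors (mm) for an isotropic pitch given in um.
# Pitch must resolve the domain: at most 1/10 of the smallest dimension.
domain_axes <- function(domain, pitch) {
  stopifnot(is.numeric(pitch), length(pitch) == 1L, pitch > 0)
  ext <- domain_extent(domain)
  h <- pitch / 1000  # mm
  if (h > min(ext) / 10) {
    stop("voxel pitch ", pitch, " um exceeds 1/10 of the smallest domain ",
         "dimension (", min(ext), " mm); refine the pitch", call. = FALSE)
  }
  n <- pmax(2L, as.integer(round(ext / h)))
  lapply(seq_along(n), function(i) (seq_len(n[i]) - (n[i] + 1) / 2) * h)
}

# Signed distance to the domain boundary, positive inside, in mm.
# X, Y, Z are arrays/vectors of physical coordinates (mm), domain centred.
domain_signed_distance <- function(domain, X, Y, Z) {
  if (domain$shape == "cylinder") {
    r <- domain$diameter / 2
    dr <- r - sqrt(X^2 + Y^2)
    dz <- domain$height / 2 - abs(Z)
    pmin(dr, dz)
  } else {
    pmin(domain$lx / 2 - abs(X),
         domain$ly / 2 - abs(Y),
         domain$lz / 2 - abs(Z))
  }
}
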