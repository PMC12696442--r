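#' Supported TPMS geometries
#'
#' The three triply periodic minimal surfaces handled by the package, each
#' approximated by the zero set of its trigonometric nodal equation.
#'
#' @return Character vector of geometry identifiers.
#' @export
#' @examples
#' tpms_geometries()
tpms_geometries <- function() c("gyroid", "diamond", "iwp")

match_geometry <- function(geometry) {
  if (!is.character(geometry) || length(geometry) != 1L ||
      !(geometry %in% tpms_geometries())) {
    stop("unknown geometry ", deparse(geometry), "; choose one of: ",
         paste(tpms_geometries(), collapse = ", "), call. = FALSE)
  }
  geometry
}

#' Evaluate a TPMS nodal equation
#'
#' Computes the implicit field value f(x, y, z) of the named minimal-surface
#' approximation at dimensionless (2*pi-periodic) coordinates.  The zero level
#' set approximates the minimal surface; the skeletal solid used for scaffolds
#' is the region where the field exceeds a threshold.
#'
#' The fields are:
#' \describe{
#'   \item{gyroid}{cos(x) sin(y) + sin(x) cos(z) + cos(y) sin(z)}
#'   \item{diamond}{sin(x) sin(y) sin(z) + sin(x) cos(y) cos(z) +
#'     cos(x) sin(y) cos(z) + cos(x) cos(y) sin(z)}
#'   \item{iwp}{2 (cos(x) cos(y) + cos(x) cos(z) + cos(y) cos(z)) -
#'     (cos(2x) + cos(2y) + cos(2z))}
#' }
#'
#' Gyroid and Diamond are odd under point inversion (f(-p) = -f(p)), which
#' pins their balanced solid fraction to exactly 1/2 at threshold 0; I-WP is
#' even.
#'
#' @param geometry One of [tpms_geometries()].
#' @param x,y,z Numeric vectors of dimensionless coordinates (recycled).
#' @return Numeric vector of field values.
#' @export
#' @examples
#' nodal_value("gyroid", 0, 0, 0)        # 0
#' nodal_value("diamond", pi/2, pi/2, pi/2)  # 1
#' nodal_value("iwp", 0, 0, 0)           # 3
nodal_value <- function(geometry, x, y, z) {
  geometry <- match_geometry(geometry)
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(z))
  switch(geometry,
    gyroid  = cos(x) * sin(y) + sin(x) * cos(z) + cos(y) * sin(z),
    diamond = sin(x) * sin(y) * sin(z) + sin(x) * cos(y) * cos(z) +
              cos(x) * sin(y) * cos(z) + cos(x) * cos(y) * sin(z),
    iwp     = 2 * (cos(x) * cos(y) + cos(x) * cos(z) + cos(y) * cos(z)) -
              (cos(2 * x) + cos(2 * y) + cos(2 * z))
  )
}
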