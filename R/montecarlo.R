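#' Monte-Carlo solid fraction of a TPMS level set
#'
#' Estimates the solid volume fraction of `{f >= t}` (skeletal) or
#' `{|f| <= t}` (sheet) over one full period by uniform sampling of the
#' dimensionless cube `[0, 2*pi)^3`.  This integrates the same indicator the
#' voxelizer counts, but without any grid, so it serves as the independent
#' volume oracle for the discretized models.  Deterministic for a fixed seed.
#'
#' @inheritParams nodal_value
#' @param threshold Level-set threshold t.
#' @param mode `"skeletal"` or `"sheet"`.
#' @param n Number of sample points (default 1e6).
#' @param seed Integer seed (default 0).
#' @return Estimated solid fraction in `[0, 1]`; the Monte-Carlo standard
#'   error is `sqrt(p (1 - p) / n)`, about 5e-4 at n = 1e6.
#' @export
mc_solid_fraction <- function(geometry, threshold = 0,
                              mode = c("skeletal", "sheet"),
                              n = 1e6, seed = 0) {
  geometry <- match_geometry(geometry)
  mode <- match.arg(mode)
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  f <- nodal_value(geometry,
                   stats::runif(n, 0, 2 * pi),
                   stats::runif(n, 0, 2 * pi),
                   stats::runif(n, 0, 2 * pi))
  if (mode == "skeletal") mean(f >= threshold) else mean(abs(f) <= threshold)
}
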