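#' Calibrate the level-set threshold to a target porosity
#'
#' Finds the threshold t at which the voxelized solid reaches a prescribed
#' void fraction, by bisection on the monotone map from t to porosity
#' (skeletal mode: nondecreasing; sheet mode: nonincreasing).  The search is
#' deterministic for fixed inputs; the initial bracket is taken from the
#' sampled field minimum and maximum.
#'
#' @inheritParams field_on_grid
#' @param target Target void fraction in (0, 1); the design default of 0.2
#'   gives an 80% solid scaffold.
#' @param mode `"skeletal"` or `"sheet"` solidification.
#' @param tol Convergence tolerance on the realized void fraction.
#' @param max_iter Maximum bisection iterations before giving up.
#' @param field Optionally a precomputed `field_grid` (then `geometry`,
#'   `domain`, `pitch`, `cell` are taken from it).
#' @param verbose If `TRUE`, print the per-iteration bracket and porosity.
#' @return A `tpms_calibration` list: `threshold`, `realized` void fraction,
#'   `iterations`, a `trace` tibble (one row per iteration), and the design
#'   metadata.
#' @export
#' @examples
#' cal <- calibrate_threshold("gyroid", domain_box(2.5, 2.5, 2.5),
#'                            target = 0.5, pitch = 100)
#' abs(cal$threshold) < 0.05  # balanced surface: t near 0
calibrate_threshold <- function(geometry, domain = domain_cylinder(),
                                target = 0.2, mode = c("skeletal", "sheet"),
                                cell = 2.5, pitch = 40,
                                tol = 1e-3, max_iter = 60L,
                                field = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(target), length(target) == 1L,
            is.numeric(tol), length(tol) == 1L, tol > 0)
  if (target <= 0 || target >= 1) {
    stop("target void fraction must lie strictly inside (0, 1), got ",
         target, call. = FALSE)
  }
  if (is.null(field)) {
    field <- field_on_grid(geometry, domain, pitch = pitch, cell = cell)
  } else {
    stopifnot(inherits(field, "field_grid"))
  }
  fv <- field$values[field$mask]
  if (length(fv) == 0L) stop("degenerate domain: empty mask", call. = FALSE)

  # void fraction as a function of t, on the voxelized field
  phi <- if (mode == "skeletal") function(t) mean(fv < t)
         else function(t) mean(abs(fv) > t)

  if (mode == "skeletal") {
    lo <- min(fv); hi <- max(fv) + abs(max(fv)) * 1e-9 + 1e-12
  } else {
    lo <- 0; hi <- max(abs(fv)) + 1e-12
  }
  ach <- sort(c(phi(lo), phi(hi)))
  if (target < ach[1] - tol || target > ach[2] + tol) {
    stop(sprintf(
      "target void fraction %.4g outside the achievable range [%.4g, %.4g] at this resolution",
      target, ach[1], ach[2]), call. = FALSE)
  }

  sgn <- if (mode == "skeletal") 1 else -1  # direction of phi in t
  trace <- vector("list", max_iter)
  t_mid <- (lo + hi) / 2
  p_mid <- phi(t_mid)
  iter <- 0L
  while (abs(p_mid - target) > tol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop(sprintf(
        "threshold calibration did not converge in %d iterations; last bracket [%.6g, %.6g], porosity %.5f vs target %.5f",
        max_iter, lo, hi, p_mid, target), call. = FALSE)
    }
    t_mid <- (lo + hi) / 2
    p_mid <- phi(t_mid)
    trace[[iter]] <- tibble::tibble(iter = iter, t_lo = lo, t_hi = hi,
                                    t = t_mid, void_fraction = p_mid)
    if (verbose) {
      message(sprintf("  iter %2d: t in [%.6g, %.6g], t = %.6g, phi = %.5f",
                      iter, lo, hi, t_mid, p_mid))
    }
    if (sgn * (p_mid - target) < 0) lo <- t_mid else hi <- t_mid
  }
  structure(
    list(threshold = t_mid, realized = p_mid, target = target,
         iterations = iter, trace = dplyr::bind_rows(trace),
         geometry = field$geometry, mode = mode, cell = field$cell,
         pitch = field$pitch, domain = field$domain, tol = tol),
    class = "tpms_calibration"
  )
}

#' @export
print.tpms_calibration <- function(x, ...) {
  cat(sprintf(
    "<calibration: %s %s, t = %.6g -> porosity %.4f (target %.3g) in %d iterations>\n",
    x$geometry, x$mode, x$threshold, x$realized, x$target, x$iterations))
  invisible(x)
}

#' Design one calibrated scaffold
#'
#' Convenience wrapper tying field sampling, threshold calibration and
#' solidification together: the usual first step of the design pipeline.
#'
#' @inheritParams calibrate_threshold
#' @param target_porosity Design void fraction (default 0.2).
#' @return A `scaffold_design`: the calibrated `voxel_model` under `$model`,
#'   the `tpms_calibration` under `$calibration`, and the retained
#'   `field_grid` under `$field` (needed for surface extraction).
#' @export
scaffold_design <- function(geometry, target_porosity = 0.2,
                            domain = domain_cylinder(), cell = 2.5,
                            pitch = 40, mode = c("skeletal", "sheet"),
                            tol = 1e-3, verbose = FALSE) {
  mode <- match.arg(mode)
  field <- field_on_grid(geometry, domain, pitch = pitch, cell = cell)
  cal <- calibrate_threshold(field = field, target = target_porosity,
                             mode = mode, tol = tol, verbose = verbose)
  model <- solidify(field, threshold = cal$threshold, mode = mode)
  structure(list(model = model, calibration = cal, field = field),
            class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  print(x$calibration)
  invisible(x)
}
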