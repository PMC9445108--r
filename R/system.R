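#' Acquisition orbit specification
#'
#' Circular or elliptical detector orbit around the axial axis.  View 0
#' places the detector along +x; views proceed counter-clockwise over
#' `arc_degrees`.  Distance is measured from the isocentre plane to the
#' collimator face along the detector normal.
#'
#' @param kind `"circular"` or `"elliptical"`.
#' @param radius_mm radius of rotation for a circular orbit (default 260,
#'   i.e. 26 cm).
#' @param semi_major_mm,semi_minor_mm elliptical orbit semi-axes (defaults
#'   250 and 175 mm; major along x).
#' @param n_views number of projection views (default 120).
#' @param arc_degrees angular coverage (default 360).
#' @return An object of class `orbit_spec`.
#' @export
orbit_spec <- function(kind = c("circular", "elliptical"), radius_mm = 260,
                       semi_major_mm = 250, semi_minor_mm = 175,
                       n_views = 120L, arc_degrees = 360) {
  kind <- match.arg(kind)
  n_views <- as.integer(n_views)
  if (n_views < 4L) stop("n_views must be >= 4")
  structure(list(kind = kind, radius_mm = radius_mm,
                 semi_major_mm = semi_major_mm, semi_minor_mm = semi_minor_mm,
                 n_views = n_views, arc_degrees = arc_degrees),
            class = "orbit_spec")
}

#' @export
print.orbit_spec <- function(x, ...) {
  if (x$kind == "circular")
    cat(sprintf("<orbit_spec> circular, R = %.0f mm, %d views over %g deg\n",
                x$radius_mm, x$n_views, x$arc_degrees))
  else
    cat(sprintf("<orbit_spec> elliptical, %0.f/%0.f mm, %d views over %g deg\n",
                x$semi_major_mm, x$semi_minor_mm, x$n_views, x$arc_degrees))
  invisible(x)
}

#' View angles of an orbit (radians)
#' @param orbit an [orbit_spec()].
#' @return numeric vector of length `n_views`.
#' @export
view_angles <- function(orbit) {
  (seq_len(orbit$n_views) - 1) * (orbit$arc_degrees / orbit$n_views) * pi / 180
}

#' Detector distance at a view angle
#'
#' Isocentre-to-collimator-face distance along the detector normal:
#' constant for a circular orbit; for an elliptical orbit the polar radius
#' of the ellipse at that angle,
#' `ab / sqrt(b^2 cos^2 + a^2 sin^2)`.
#'
#' @param orbit an [orbit_spec()].
#' @param view_angle_deg angle(s) in degrees in `[0, 360)`.
#' @return distance(s) in mm.
#' @export
detector_distance <- function(orbit, view_angle_deg) {
  th <- view_angle_deg * pi / 180
  if (orbit$kind == "circular") {
    rep(orbit$radius_mm, length(th))
  } else {
    a <- orbit$semi_major_mm; b <- orbit$semi_minor_mm
    a * b / sqrt(b^2 * cos(th)^2 + a^2 * sin(th)^2)
  }
}

#' Detector sampling specification
#'
#' Radial/axial binning of the projection data.  The rotation-based
#' projector requires the detector to mirror the image grid
#' (`n_bins = ny`, `bin_mm = voxel_mm`); [detector_from_grid()] builds the
#' matched specification.
#'
#' @param n_bins,bin_mm radial bin count and size (mm).
#' @param n_slices,slice_mm axial slice count and thickness (mm).
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(n_bins, bin_mm, n_slices, slice_mm) {
  if (bin_mm <= 0 || slice_mm <= 0) stop("bin/slice sizes must be > 0")
  structure(list(n_bins = as.integer(n_bins), bin_mm = bin_mm,
                 n_slices = as.integer(n_slices), slice_mm = slice_mm),
            class = "detector_spec")
}

#' @rdname detector_spec
#' @param grid a [grid_spec()].
#' @export
detector_from_grid <- function(grid) {
  detector_spec(grid$ny, grid$voxel_mm, grid$nz, grid$voxel_mm)
}

#' Distance-dependent collimator resolution model
#'
#' Linear FWHM model of a parallel-hole collimator,
#' `FWHM(d) = fwhm0 + slope * d`, converted to a Gaussian sigma by
#' `sigma = FWHM / 2.354820045`.  Defaults approximate an LEHR collimator
#' (7.5 mm FWHM at 100 mm).
#'
#' @param fwhm0_mm resolution at zero distance (mm, >= 0).
#' @param slope mm of FWHM per mm of distance (>= 0).
#' @return An object of class `collimator_model`.
#' @export
collimator_model <- function(fwhm0_mm = 3.0, slope = 0.045) {
  if (fwhm0_mm < 0 || slope < 0) stop("fwhm0_mm and slope must be >= 0")
  structure(list(fwhm0_mm = fwhm0_mm, slope = slope),
            class = "collimator_model")
}

#' Collimator Gaussian sigma at a distance
#' @param model a [collimator_model()].
#' @param distance_mm distance(s) from the collimator face (mm, >= 0).
#' @return sigma in mm.
#' @export
collimator_sigma <- function(model, distance_mm) {
  if (any(distance_mm < 0)) stop("distance_mm must be >= 0")
  (model$fwhm0_mm + model$slope * distance_mm) / 2.354820045
}
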