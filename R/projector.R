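#' Sinogram container
#'
#' Projection data (radial bins x axial slices x views) bound to an
#' acquisition geometry, with a provenance list recording how the counts
#' were produced (components, scale history, seeds).
#'
#' @param counts 3D array `c(n_bins, n_slices, n_views)`, non-negative.
#' @param orbit an [orbit_spec()].
#' @param detector a [detector_spec()].
#' @param provenance list of free-form provenance entries.
#' @return An object of class `sinogram`.
#' @export
sinogram <- function(counts, orbit, detector, provenance = list()) {
  if (any(!is.finite(counts))) stop("sinogram counts must be finite")
  if (any(counts < 0)) stop("sinogram counts must be non-negative")
  d <- dim(counts)
  if (length(d) != 3 || d[1] != detector$n_bins || d[2] != detector$n_slices ||
      d[3] != orbit$n_views)
    stop("counts shape inconsistent with geometry")
  structure(list(counts = counts, orbit = orbit, detector = detector,
                 provenance = provenance), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<sinogram> %d bins x %d slices x %d views; total counts %.6g\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a$orbit), unclass(b$orbit))) &&
    isTRUE(all.equal(unclass(a$detector), unclass(b$detector)))
}

#' Simulate projection data (forward projection)
#'
#' Rotation-based forward model: for each view the volume is resampled into
#' the detector frame (bilinear, zero padding); each constant-distance plane
#' is blurred with a 2D Gaussian of `collimator_sigma(distance)` in the
#' transaxial-bin and axial directions, then (for `attenuation_mode =
#' "full"`) multiplied by the cumulative attenuation survival factor
#' `exp(-int mu)` from that plane to the detector (midpoint rule) and
#' accumulated into the bins.  The operator is linear in the activity.
#'
#' @param activity activity [volume_image()] (square transaxial grid).
#' @param mu attenuation [volume_image()] on the same grid, or `NULL`.
#' @param orbit an [orbit_spec()]; `n_views` views over the arc.
#' @param collimator a [collimator_model()].
#' @param attenuation_mode `"full"` (cumulative plane-by-plane attenuation)
#'   or `"none"`.
#' @return a [sinogram()] with detector sampling mirroring the grid.
#' @export
forward_project <- function(activity, mu = NULL, orbit,
                            collimator = collimator_model(),
                            attenuation_mode = c("full", "none")) {
  attenuation_mode <- match.arg(attenuation_mode)
  g <- activity$grid
  if (g$nx != g$ny) stop("square transaxial grid required")
  atten <- attenuation_mode == "full"
  if (atten) {
    if (is.null(mu)) stop("mu required for attenuation_mode = 'full'")
    if (!same_grid(activity, mu)) stop("activity and mu grids differ")
  }
  ang <- view_angles(orbit)
  radii <- detector_distance(orbit, ang * 180 / pi)
  muv <- if (atten) mu$values else array(0, dim(activity$values))
  counts <- cpp_forward_blur(activity$values, muv, ang, radii, g$voxel_mm,
                             collimator$fwhm0_mm, collimator$slope, atten)
  sinogram(counts, orbit, detector_from_grid(g),
           provenance = list(list(op = "forward_project",
                                  attenuation = attenuation_mode,
                                  collimator = unclass(collimator),
                                  total = sum(counts))))
}

#' Unblurred (geometric) forward projection
#'
#' The reconstruction-side system model: no collimator blur, voxelwise
#' central-ray attenuation factors (`ac_mode = "simple"`) or none.  Exposed
#' for data-fidelity and likelihood checks.
#'
#' @inheritParams forward_project
#' @param ac_mode `"simple"` or `"none"`.
#' @return a [sinogram()].
#' @export
forward_project_geometric <- function(activity, mu = NULL, orbit,
                                      ac_mode = c("simple", "none")) {
  ac_mode <- match.arg(ac_mode)
  g <- activity$grid
  atten <- ac_mode == "simple"
  if (atten && is.null(mu)) stop("mu required for ac_mode = 'simple'")
  muv <- if (atten) mu$values else array(0, dim(activity$values))
  counts <- cpp_forward_geom(activity$values, muv, view_angles(orbit),
                             g$voxel_mm, atten)
  sinogram(counts, orbit, detector_from_grid(g),
           provenance = list(list(op = "forward_project_geometric",
                                  ac_mode = ac_mode)))
}

#' Weighted sum of sinograms
#'
#' Realises component-wise simulation: phantom components (background,
#' lesion excess, perturbation point) are projected separately and the
#' sinograms combined with scales, e.g. a ground-truth TBR maps to scaling
#' the lesion-excess component by `(TBR - 1) * background`.
#'
#' @param parts list of parts; each part is either a [sinogram()] (scale 1)
#'   or `list(sino, scale)`.
#' @return a [sinogram()] on the shared geometry.
#' @export
combine_sinograms <- function(parts) {
  norm <- lapply(parts, function(p) {
    if (inherits(p, "sinogram")) list(sino = p, scale = 1)
    else list(sino = p[[1]], scale = p[[2]])
  })
  ref <- norm[[1]]$sino
  acc <- array(0, dim(ref$counts))
  prov <- list()
  for (p in norm) {
    if (!same_geometry(p$sino, ref)) stop("sinogram geometry mismatch")
    acc <- acc + p$scale * p$sino$counts
    prov <- c(prov, list(list(op = "combine", scale = p$scale,
                              part = p$sino$provenance)))
  }
  sinogram(pmax(acc, 0), ref$orbit, ref$detector, provenance = prov)
}

#' Rescale a sinogram to a target total count
#'
#' @param s a [sinogram()] with positive total.
#' @param target_total desired sum of all projections (e.g. 5e6 for bone
#'   scan count levels, 22e6 for Tektrotyd).
#' @return a [sinogram()] whose counts sum to `target_total`; the applied
#'   scale factor is recorded in provenance as `count_scale`.
#' @export
scale_to_total_counts <- function(s, target_total) {
  tot <- sum(s$counts)
  if (tot <= 0) stop("cannot scale an all-zero sinogram")
  sc <- target_total / tot
  sinogram(s$counts * sc, s$orbit, s$detector,
           provenance = c(s$provenance,
                          list(list(op = "scale_to_total_counts",
                                    count_scale = sc,
                                    target_total = target_total))))
}

#' Add Poisson noise to a sinogram
#'
#' Independent Poisson draw per bin with the input bin as mean; the seed is
#' recorded in provenance.  The RNG state of the caller is left untouched.
#'
#' @param s a [sinogram()].
#' @param seed integer seed.
#' @return a noisy [sinogram()].
#' @export
add_poisson_noise <- function(s, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  noisy <- array(rpois(length(s$counts), s$counts), dim(s$counts))
  sinogram(noisy, s$orbit, s$detector,
           provenance = c(s$provenance,
                          list(list(op = "add_poisson_noise", seed = seed))))
}

#' Rebin a sinogram to coarser detector sampling
#'
#' Sums `factor x factor` blocks of (radial bin, axial slice), converting a
#' fine-grid simulation onto clinical detector bins; counts are preserved
#' exactly.
#'
#' @param s a [sinogram()].
#' @param factor integer block size per detector axis.
#' @return a [sinogram()] with `n_bins/factor` bins of size
#'   `bin_mm * factor`.
#' @export
rebin_sinogram <- function(s, factor) {
  factor <- as.integer(factor)
  d <- dim(s$counts)
  if (any(d[1:2] %% factor != 0)) stop("detector dims not divisible by factor")
  nb <- d[1] %/% factor; ns <- d[2] %/% factor
  v <- s$counts
  dim(v) <- c(factor, nb, factor, ns, d[3])
  counts <- apply(v, c(2, 4, 5), sum)
  det <- detector_spec(nb, s$detector$bin_mm * factor,
                       ns, s$detector$slice_mm * factor)
  sinogram(counts, s$orbit, det,
           provenance = c(s$provenance,
                          list(list(op = "rebin_sinogram", factor = factor))))
}
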