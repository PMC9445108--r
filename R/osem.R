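#' OSEM reconstruction settings
#'
#' @param n_subsets number of ordered subsets (default 10); must divide the
#'   number of views.
#' @param n_iterations full iterations (default 20, i.e. 200 updates with 10
#'   subsets; one update = one subset pass).
#' @param checkpoints update numbers at which images are kept (default every
#'   10 updates to `n_subsets * n_iterations`).
#' @param ac_mode attenuation correction in the system model: `"simple"`
#'   (voxelwise central-ray attenuation factors from an unblurred line
#'   integral of mu, no blur-path modelling) or `"none"`.  The simulator's
#'   "full" blurred-plane attenuation is deliberately not reproduced here,
#'   giving the intended model mismatch.
#' @param epsilon guard added to forward projections before division.
#' @param sens_rel_thresh sensitivity voxels below this fraction of the
#'   maximum are excluded from updates.
#' @return An object of class `recon_settings`.
#' @export
recon_settings <- function(n_subsets = 10L, n_iterations = 20L,
                           checkpoints = NULL,
                           ac_mode = c("simple", "none"),
                           epsilon = 1e-12, sens_rel_thresh = 1e-8) {
  ac_mode <- match.arg(ac_mode)
  n_subsets <- as.integer(n_subsets); n_iterations <- as.integer(n_iterations)
  total <- n_subsets * n_iterations
  if (is.null(checkpoints)) checkpoints <- seq(10L, total, by = 10L)
  checkpoints <- sort(unique(as.integer(checkpoints)))
  if (any(checkpoints < 1L) || any(checkpoints > total))
    stop("checkpoints must lie in [1, n_subsets * n_iterations]")
  structure(list(n_subsets = n_subsets, n_iterations = n_iterations,
                 checkpoints = checkpoints, ac_mode = ac_mode,
                 epsilon = epsilon, sens_rel_thresh = sens_rel_thresh),
            class = "recon_settings")
}

#' Interleaved subset partition of views
#'
#' Subset `k` (0-based) takes views `k, k + n_subsets, ...`, maximising the
#' angular spread within each subset; deterministic order.
#'
#' @param n_views total view count.
#' @param n_subsets subset count; must divide `n_views`.
#' @return list of integer vectors of 1-based view indices.
#' @export
subset_partition <- function(n_views, n_subsets) {
  if (n_views %% n_subsets != 0)
    stop("n_views (", n_views, ") not divisible by n_subsets (", n_subsets, ")")
  lapply(seq_len(n_subsets) - 1L,
         function(s) seq.int(s + 1L, n_views, by = n_subsets))
}

#' Cylindrical reconstruction FOV mask
#'
#' The inscribed transaxial cylinder of the grid; the initial image is
#' uniform 1 inside and 0 outside.
#'
#' @param grid a [grid_spec()].
#' @return logical array.
#' @export
fov_mask <- function(grid) {
  ax <- grid_axes(grid)
  r <- (min(grid$nx, grid$ny) / 2 - 0.5) * grid$voxel_mm
  xy <- outer(ax$x^2, ax$y^2, "+") <= r^2
  array(rep(xy, grid$nz), c(grid$nx, grid$ny, grid$nz))
}

#' OSEM reconstruction
#'
#' Multiplicative OSEM with an unblurred rotation-based projector (no
#' resolution modelling) and attenuation per `ac_mode`, the deliberate
#' mismatch with the blurred simulator.  Subset sensitivity images are
#' precomputed; all divisions are epsilon-guarded; the subset order is fixed
#' so identical inputs give bit-identical checkpoints.
#'
#' @param s measured [sinogram()].
#' @param mu attenuation [volume_image()] on the reconstruction grid, or
#'   `NULL` for `ac_mode = "none"`.
#' @param grid reconstruction [grid_spec()] (must mirror the detector
#'   sampling).
#' @param settings a [recon_settings()].
#' @return An object of class `update_series`: list with `images` (named
#'   list of [volume_image()] keyed by update number), `settings`, and
#'   `geometry`.
#' @export
osem_reconstruct <- function(s, mu = NULL, grid, settings = recon_settings()) {
  if (s$orbit$n_views %% settings$n_subsets != 0)
    stop("n_views not divisible by n_subsets")
  if (s$detector$n_bins != grid$ny || s$detector$n_slices != grid$nz ||
      abs(s$detector$bin_mm - grid$voxel_mm) > 1e-9)
    stop("detector sampling does not mirror the reconstruction grid")
  atten <- settings$ac_mode == "simple"
  if (atten) {
    if (is.null(mu)) stop("mu required for ac_mode = 'simple'")
    if (!identical(dim(mu$values), c(grid$nx, grid$ny, grid$nz)))
      stop("mu grid does not match reconstruction grid")
  }
  init <- fov_mask(grid) * 1.0
  muv <- if (atten) mu$values else array(0, c(grid$nx, grid$ny, grid$nz))
  cps <- settings$checkpoints
  imgs <- cpp_osem(s$counts, muv, view_angles(s$orbit), grid$voxel_mm,
                   settings$n_subsets, settings$n_iterations,
                   as.integer(cps), init, atten,
                   settings$epsilon, settings$sens_rel_thresh)
  images <- setNames(lapply(imgs, function(a) volume_image(pmax(a, 0), grid)),
                     as.character(cps))
  structure(list(images = images, settings = settings,
                 geometry = list(orbit = s$orbit, detector = s$detector),
                 provenance = s$provenance),
            class = "update_series")
}

#' @export
print.update_series <- function(x, ...) {
  cat(sprintf("<update_series> %d checkpoints (updates %s); %d subsets x %d iterations, ac_mode=%s\n",
              length(x$images), paste(range(as.integer(names(x$images))), collapse = ".."),
              x$settings$n_subsets, x$settings$n_iterations, x$settings$ac_mode))
  invisible(x)
}

#' Poisson log-likelihood of an image given measured data
#'
#' `sum(y * log(yhat) - yhat)` (omitting the constant `log(y!)` term), with
#' `yhat` the geometric forward projection of the image under the
#' reconstruction system model.  Used to verify MLEM monotonicity.
#'
#' @param s measured [sinogram()].
#' @param img image [volume_image()].
#' @param mu attenuation map or `NULL`.
#' @param ac_mode `"simple"` or `"none"`.
#' @return scalar log-likelihood.
#' @export
poisson_loglik <- function(s, img, mu = NULL, ac_mode = c("simple", "none")) {
  ac_mode <- match.arg(ac_mode)
  yhat <- forward_project_geometric(img, mu, s$orbit, ac_mode)$counts
  y <- s$counts
  keep <- y > 0
  sum(y[keep] * log(pmax(yhat[keep], 1e-300))) - sum(yhat)
}
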