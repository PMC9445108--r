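# End-to-end drivers: scene assembly, the perturbation pipeline (simulate,
# calibrate, paired reconstruction, fit), and PVC of a checkpoint series.

#' Assemble a simple elliptical-cylinder scene
#'
#' Unit background cylinder with an optional spherical lesion, attenuation
#' map, and the component volumes used for component-wise projection (the
#' lesion excess is projected separately and scaled to realise TBRs in data
#' space).
#'
#' @param grid a [grid_spec()].
#' @param lesion a [lesion_spec()] or `NULL`.
#' @param major_mm,minor_mm transaxial semi-axes of the background.
#' @param length_mm axial length; default 216 mm when the grid covers it,
#'   otherwise 180 mm (the reduced-scale axial FOV).
#' @param mu_per_mm body attenuation coefficient.
#' @return list with `activity` (ground truth), `background`,
#'   `lesion_indicator`, `mu`, `lesion_mask`, `body_mask`, `gt_rmv`,
#'   `lesion`, and geometry metadata.
#' @export
simple_scene <- function(grid, lesion = NULL, major_mm = 152, minor_mm = 108,
                         length_mm = NULL, mu_per_mm = 0.0154) {
  if (is.null(length_mm))
    length_mm <- if (grid$nz * grid$voxel_mm >= 216) 216 else 180
  bg <- make_elliptical_cylinder(grid, major_mm, minor_mm, length_mm, 1)
  act <- bg
  lmask <- NULL; gt_rmv <- NA_real_; lind <- NULL
  if (!is.null(lesion)) {
    act <- add_lesion(bg, lesion, 1)
    lmask <- lesion_mask(grid, lesion)
    gt_rmv <- regional_mean(act, lmask)
    lind <- volume_image(lmask * 1.0, grid)
  }
  list(activity = act, background = bg, lesion_indicator = lind,
       mu = make_attenuation_map(bg, mu_per_mm),
       lesion_mask = lmask, body_mask = bg$values > 0,
       gt_rmv = gt_rmv, lesion = lesion,
       meta = list(major_mm = major_mm, minor_mm = minor_mm,
                   length_mm = length_mm, mu_per_mm = mu_per_mm))
}

#' Simulate the measured sinogram of a scene from its components
#'
#' Projects the background and the unit lesion indicator separately and
#' combines them with the TBR-derived scale, reproducing component-wise
#' sinogram scaling.  A precomputed background sinogram can be supplied to
#' cache the expensive part across a lesion sweep.
#'
#' @param scene a [simple_scene()].
#' @param orbit an [orbit_spec()].
#' @param collimator a [collimator_model()].
#' @param background_sino optional cached background [sinogram()].
#' @return list with `sino` (noise-free measured data) and
#'   `background_sino`.
#' @export
simulate_scene_sinogram <- function(scene, orbit,
                                    collimator = collimator_model(),
                                    background_sino = NULL) {
  if (is.null(background_sino))
    background_sino <- forward_project(scene$background, scene$mu, orbit,
                                       collimator, "full")
  if (is.null(scene$lesion_indicator)) {
    return(list(sino = background_sino, background_sino = background_sino))
  }
  les_sino <- forward_project(scene$lesion_indicator, scene$mu, orbit,
                              collimator, "full")
  sino <- combine_sinograms(list(background_sino,
                                 list(les_sino, scene$lesion$tbr - 1)))
  list(sino = sino, background_sino = background_sino)
}

#' Run the perturbation pipeline on measured data
#'
#' Simulates the point-source sinogram, optionally applies count scaling
#' and Poisson noise to the measured data, reconstructs unperturbed and
#' perturbed data identically, and fits the PSF at every checkpoint.
#' Reconstructed images are returned in ground-truth units (any count
#' scaling is divided back out, using the known simulation scale).
#'
#' @param base_sino noise-free measured [sinogram()] in ground-truth units.
#' @param mu attenuation [volume_image()].
#' @param grid reconstruction [grid_spec()].
#' @param point_mm perturbation point position (mm).
#' @param collimator the [collimator_model()] of the simulator.
#' @param settings [recon_settings()].
#' @param noise `NULL` for noise-free, else `list(total_counts=, seed=)`.
#' @param cfg a [fit_config()].
#' @return list with `psf` (list of [estimate_psf()] results keyed by
#'   update, each carrying its achieved contrast), `base` (unperturbed
#'   series in GT units), `diff` (difference images), `scale`, `contrast`
#'   (at the final update), `count_scale`, `point_mm`.
#' @export
run_perturbation_case <- function(base_sino, mu, grid, point_mm,
                                  collimator = collimator_model(),
                                  settings = recon_settings(),
                                  noise = NULL, cfg = fit_config()) {
  # theta is fixed from the intended point position (0 on the axes / at the
  # isocentre); the fit position snaps to the actual single-voxel source so
  # the fit planes pass exactly through voxel centres (no mid-voxel
  # interpolation blur)
  if (is.null(cfg$theta_deg))
    cfg$theta_deg <- point_theta(point_mm) * 180 / pi
  point_mm <- index_to_world(grid, world_to_index(grid, point_mm))
  point_src <- make_point_source(grid, point_mm, 1)
  point_sino <- forward_project(point_src, mu, base_sino$orbit, collimator,
                                if (is.null(mu)) "none" else "full")
  count_scale <- 1
  meas <- base_sino
  if (!is.null(noise)) {
    meas <- scale_to_total_counts(base_sino, noise$total_counts)
    count_scale <- noise$total_counts / sum(base_sino$counts)
    meas <- add_poisson_noise(meas, noise$seed)
    point_sino <- sinogram(point_sino$counts * count_scale, point_sino$orbit,
                           point_sino$detector, point_sino$provenance)
  }
  base_series <- osem_reconstruct(meas, mu, grid, settings)
  calib <- calibrate_point_scale(point_sino, meas, base_series, mu, grid,
                                 settings, point_mm,
                                 point_amplitude = count_scale,
                                 collimator = collimator)
  pd <- perturb_and_difference(meas, point_sino, calib$scale, mu, grid,
                               settings, base_series)
  idx <- world_to_index(grid, point_mm)
  psf <- lapply(names(pd$diff), function(u) {
    est <- estimate_psf(pd$diff[[u]], point_mm, cfg)
    est$update <- as.integer(u)
    bv <- pd$base$images[[u]]$values[idx[1], idx[2], idx[3]]
    est$contrast <- if (bv > 0) local_peak(pd$diff[[u]]$values, idx) / bv else Inf
    if (est$contrast > 0.1) est$valid <- FALSE
    est
  })
  names(psf) <- names(pd$diff)
  base_gt_units <- pd$base
  if (count_scale != 1) {
    base_gt_units$images <- lapply(pd$base$images, function(im)
      volume_image(im$values / count_scale, grid))
  }
  list(psf = psf, base = base_gt_units, diff = pd$diff,
       scale = calib$scale, contrast = calib$contrast,
       count_scale = count_scale, point_mm = point_mm,
       calibration_passes = calib$passes)
}

#' Apply STC across a checkpoint series
#'
#' For each requested checkpoint, builds the kernel from that checkpoint's
#' PSF estimate and corrects the reconstruction, reporting uncorrected and
#' corrected target RMVs.
#'
#' @param case result of [run_perturbation_case()].
#' @param target logical target mask.
#' @param body logical body-support mask.
#' @param settings an [stc_settings()].
#' @param updates integer vector of checkpoint update numbers (default all).
#' @return data.frame with columns `update`, `rmv_uncorrected`,
#'   `rmv_corrected`, `fwhm_radial_mm`, `fwhm_tangential_mm`,
#'   `fwhm_axial_mm`, `contrast`, `psf_valid`.
#' @export
pvc_over_series <- function(case, target, body, settings = stc_settings(),
                            updates = NULL) {
  grid <- case$base$images[[1]]$grid
  masks <- region_masks(target, body)
  av <- as.integer(names(case$base$images))
  if (is.null(updates)) updates <- av
  updates <- intersect(as.integer(updates), av)
  rows <- lapply(updates, function(u) {
    key <- as.character(u)
    img <- case$base$images[[key]]
    psf <- case$psf[[key]]
    kern <- psf_kernel(psf, grid)
    res <- stc_correct(img, masks, kern, settings)
    data.frame(update = u,
               rmv_uncorrected = regional_mean(img, target),
               rmv_corrected = regional_mean(res$corrected, target),
               fwhm_radial_mm = psf$fwhm_radial_mm,
               fwhm_tangential_mm = psf$fwhm_tangential_mm,
               fwhm_axial_mm = psf$fwhm_axial_mm,
               contrast = psf$contrast,
               psf_valid = psf$valid)
  })
  do.call(rbind, rows)
}

#' STC on a local subvolume around the target
#'
#' Crops the image, masks and correction to a padded bounding box around
#' the target (background = body support within the box minus the target).
#' The kernel's Gaussian locality makes the influence of background beyond
#' a few kernel widths negligible, so the target RMV matches the
#' whole-body-background correction while large (fine-grid) volumes stay
#' affordable.
#'
#' @inheritParams pvc_over_series
#' @param f observed [volume_image()].
#' @param kernel a [psf_kernel()] built on `f`'s grid.
#' @param margin_mm padding around the target bounding box (default 64 mm,
#'   several kernel widths).
#' @return a `correction_result` (see [stc_correct()]) for the cropped
#'   subvolume, with the crop index ranges in `$crop`.
#' @export
stc_correct_local <- function(f, target, body, kernel,
                              settings = stc_settings(), margin_mm = 64) {
  g <- f$grid
  target <- as_mask(target, g)
  body <- as_mask(body, g)
  idx <- which(target, arr.ind = TRUE)
  mvox <- ceiling(margin_mm / g$voxel_mm)
  n <- c(g$nx, g$ny, g$nz)
  lo <- pmax(apply(idx, 2, min) - mvox, 1L)
  hi <- pmin(apply(idx, 2, max) + mvox, n)
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (any(hi - lo + 1 <= dim(kernel)))
    stop("crop smaller than the kernel; increase margin_mm")
  gc <- grid_spec(hi[1] - lo[1] + 1, hi[2] - lo[2] + 1, hi[3] - lo[3] + 1,
                  g$voxel_mm)
  fc <- volume_image(sub(f$values), gc)
  masks <- region_masks(sub(target), sub(body) | sub(target))
  res <- stc_correct(fc, masks, kernel, settings)
  res$crop <- list(lo = lo, hi = hi)
  res
}

#' Fine-grid torso perturbation + PVC pipeline
#'
#' The anthropomorphic workflow: the scene is generated on a fine grid,
#' forward projected there and rebinned to the clinical detector sampling;
#' reconstruction runs on the coarse grid; the unperturbed and difference
#' images are then resampled onto the fine ground-truth grid before PSF
#' estimation, segmentation and STC.
#'
#' @param scenario,lesions,bladder_multiplier passed to [make_torso_scene()]
#'   (on the fine grid).
#' @param target name of the lesion to quantify.
#' @param grid coarse reconstruction [grid_spec()].
#' @param orbit an [orbit_spec()] (elliptical by default for torso studies).
#' @param collimator a [collimator_model()].
#' @param settings [recon_settings()].
#' @param fine_factor fine-grid refinement per axis (default 2: 2 mm
#'   generation voxels under a 4 mm reconstruction).
#' @param noise `NULL` or `list(total_counts=, seed=)`.
#' @param updates checkpoints at which to apply STC (default all).
#' @param stc an [stc_settings()].
#' @return list with `pvc` (data.frame: update, uncorrected/corrected RMV
#'   on the fine grid, percent deviations, FWHMs, contrast), `gt_rmv`,
#'   `psf` (fine-grid estimates), `contrast`, `scale`, `scene` metadata.
#' @export
run_torso_case <- function(scenario, lesions, target, grid,
                           orbit = orbit_spec("elliptical", n_views = 60),
                           collimator = collimator_model(),
                           settings = recon_settings(),
                           fine_factor = 2L, bladder_multiplier = 15,
                           noise = NULL, updates = NULL,
                           stc = stc_settings()) {
  f <- as.integer(fine_factor)
  fine <- grid_spec(grid$nx * f, grid$ny * f, grid$nz * f, grid$voxel_mm / f)
  scene <- make_torso_scene(scenario, fine, lesions = lesions,
                            bladder_multiplier = bladder_multiplier)
  centre <- scene$lesion_centres[[target]]
  theta_deg <- point_theta(centre) * 180 / pi
  pt <- index_to_world(fine, world_to_index(fine, centre))
  sino <- rebin_sinogram(forward_project(scene$activity, scene$attenuation,
                                         orbit, collimator, "full"), f)
  point_sino <- rebin_sinogram(forward_project(
    make_point_source(fine, pt, 1), scene$attenuation, orbit, collimator,
    "full"), f)
  mu_coarse <- block_average(scene$attenuation, f)
  count_scale <- 1
  meas <- sino
  if (!is.null(noise)) {
    meas <- scale_to_total_counts(sino, noise$total_counts)
    count_scale <- noise$total_counts / sum(sino$counts)
    meas <- add_poisson_noise(meas, noise$seed)
    point_sino <- sinogram(point_sino$counts * count_scale, point_sino$orbit,
                           point_sino$detector, point_sino$provenance)
  }
  base_series <- osem_reconstruct(meas, mu_coarse, grid, settings)
  calib <- calibrate_point_scale(point_sino, meas, base_series, mu_coarse,
                                 grid, settings, pt,
                                 point_amplitude = count_scale,
                                 collimator = collimator)
  pd <- perturb_and_difference(meas, point_sino, calib$scale, mu_coarse,
                               grid, settings, base_series)
  av <- as.integer(names(pd$diff))
  updates <- if (is.null(updates)) av else intersect(as.integer(updates), av)
  gt <- scene$lesion_values[[target]]
  tmask <- scene$lesion_masks[[target]]
  cfg <- fit_config(theta_deg = theta_deg)
  idxc <- world_to_index(grid, pt)
  psf_list <- list()
  rows <- lapply(updates, function(u) {
    key <- as.character(u)
    diff_f <- resample_to_grid(pd$diff[[key]], fine)
    base_f <- resample_to_grid(pd$base$images[[key]], fine)
    if (count_scale != 1)
      base_f <- volume_image(base_f$values / count_scale, fine)
    est <- estimate_psf(diff_f, pt, cfg)
    est$update <- u
    bv <- pd$base$images[[key]]$values[idxc[1], idxc[2], idxc[3]]
    est$contrast <- if (bv > 0)
      local_peak(pd$diff[[key]]$values, idxc) / bv else Inf
    if (est$contrast > 0.1) est$valid <- FALSE
    psf_list[[key]] <<- est
    kern <- psf_kernel(est, fine)
    res <- stc_correct_local(base_f, tmask, scene$body_mask, kern, stc)
    sub <- function(a) a[res$crop$lo[1]:res$crop$hi[1],
                         res$crop$lo[2]:res$crop$hi[2],
                         res$crop$lo[3]:res$crop$hi[3]]
    tm <- sub(tmask)
    data.frame(update = u,
               rmv_uncorrected = mean(base_f$values[tmask]),
               rmv_corrected = mean(res$corrected$values[tm]),
               fwhm_radial_mm = est$fwhm_radial_mm,
               fwhm_tangential_mm = est$fwhm_tangential_mm,
               fwhm_axial_mm = est$fwhm_axial_mm,
               contrast = est$contrast, psf_valid = est$valid)
  })
  pvc <- do.call(rbind, rows)
  pvc$gt_rmv <- gt
  pvc$dev_uncorrected_pct <- percent_deviation(pvc$rmv_uncorrected, gt)
  pvc$dev_corrected_pct <- percent_deviation(pvc$rmv_corrected, gt)
  list(pvc = pvc, gt_rmv = gt, psf = psf_list, contrast = calib$contrast,
       scale = calib$scale, count_scale = count_scale,
       meta = c(scene$meta, list(target = target, point_mm = pt,
                                 fine_factor = f)))
}
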