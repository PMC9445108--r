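# Accuracy metrics and scripted experiment drivers: local RMSE of the
# reconstruction against the PSF-blurred ground truth, percent deviations
# of regional mean values, and the figure-analogue experiments.

#' Local evaluation region around a lesion
#'
#' The lesion mask dilated by a Euclidean radius (default twice the
#' expected FWHM), the "local volume" over which the RMSE is computed.
#'
#' @param mask logical lesion mask.
#' @param grid a [grid_spec()].
#' @param dilate_mm dilation radius in mm.
#' @return An object of class `evaluation_region`: list with `mask`
#'   (logical array), `N` (voxel count), `dilate_mm`.
#' @export
evaluation_region <- function(mask, grid, dilate_mm) {
  stopifnot(any(mask))
  r <- max(dilate_mm, 0)
  out <- mask
  if (r > 0) {
    rv <- ceiling(r / grid$voxel_mm)
    kg <- grid_spec(max(8, 2 * rv + 1), max(8, 2 * rv + 1),
                    max(8, 2 * rv + 1), grid$voxel_mm)
    ball <- sphere_mask(kg, c(0, 0, 0), r) * 1.0
    ko <- 2 * rv + 1
    ball <- ball[seq_len(ko), seq_len(ko), seq_len(ko), drop = FALSE]
    out <- fft_convolve3(mask * 1.0, array(ball, c(ko, ko, ko))) > 0.5
    out <- out | mask
  }
  structure(list(mask = out, N = sum(out), dilate_mm = r),
            class = "evaluation_region")
}

#' Local root-mean-square error
#'
#' `sqrt(mean((R_i - C_i)^2))` over the voxels of the evaluation region,
#' with `R` the reconstruction and `C` the reference (typically the ground
#' truth convolved with an estimated PSF).
#'
#' @param recon,reference [volume_image()]s on the same grid.
#' @param region an [evaluation_region()] (or logical mask).
#' @return scalar RMSE.
#' @export
rmse_local <- function(recon, reference, region) {
  if (!same_grid(recon, reference)) stop("grid mismatch")
  m <- if (inherits(region, "evaluation_region")) region$mask else region
  m <- as_mask(m, recon$grid)
  if (!any(m)) stop("empty evaluation region")
  sqrt(mean((recon$values[m] - reference$values[m])^2))
}

#' Percent deviation from ground truth
#'
#' @param value measured value(s).
#' @param gt ground-truth value (non-zero).
#' @return `100 * (value - gt) / gt`.
#' @export
percent_deviation <- function(value, gt) {
  if (any(gt == 0)) stop("ground truth must be non-zero")
  100 * (value - gt) / gt
}

experiment_defaults <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (scale == "reduced") {
    list(scale = scale,
         grid = grid_spec(96, 96, 48, 4),
         orbit = orbit_spec("circular", radius_mm = 260, n_views = 60),
         collimator = collimator_model(),
         settings = recon_settings(10L, 20L),
         total_counts = 5e6)
  } else {
    list(scale = scale,
         grid = grid_spec(128, 128, 64, 4),
         orbit = orbit_spec("circular", radius_mm = 260, n_views = 120),
         collimator = collimator_model(),
         settings = recon_settings(10L, 20L),
         total_counts = 5e6)
  }
}

resolve_config <- function(config) {
  base <- experiment_defaults(if (is.null(config$scale)) "reduced" else config$scale)
  utils::modifyList(base, config)
}

psf_rows <- function(psf_list, extra = list()) {
  rows <- lapply(psf_list, function(p) {
    cbind(data.frame(update = p$update,
                     fwhm_radial_mm = p$fwhm_radial_mm,
                     sd_radial_mm = p$sd_radial_mm,
                     fwhm_tangential_mm = p$fwhm_tangential_mm,
                     sd_tangential_mm = p$sd_tangential_mm,
                     fwhm_axial_mm = p$fwhm_axial_mm,
                     sd_axial_mm = p$sd_axial_mm,
                     contrast = p$contrast, psf_valid = p$valid),
          as.data.frame(extra))
  })
  do.call(rbind, rows)
}

with_provenance <- function(df, cfg, seed = NA_integer_) {
  attr(df, "provenance") <- list(
    scale = cfg$scale, grid = unclass(cfg$grid), orbit = unclass(cfg$orbit),
    collimator = unclass(cfg$collimator),
    settings = unclass(cfg$settings), seed = seed)
  df
}

#' Run a named scripted experiment
#'
#' Reduced- or full-scale drivers behind the package's figure analogues.
#' Each returns a data.frame carrying a `provenance` attribute (geometry,
#' settings, seeds) sufficient to regenerate it exactly.
#'
#' Available names: `fwhm_vs_updates`, `fwhm_vs_contrast_size`,
#' `point_position_in_lesion`, `rmse_psf_choice`, `pvc_simple`,
#' `pvc_torso`, `bladder_sensitivity`, `ring_phantom`.
#'
#' @param name experiment name.
#' @param config list overriding the defaults; recognised entries include
#'   `scale` ("reduced"/"full"), `grid`, `orbit`, `collimator`, `settings`,
#'   `total_counts`, `seed`, and per-experiment entries (`radii_mm`,
#'   `tbrs`, `positions`, `noise`, `lesions`, ...).
#' @return data.frame of results with a `provenance` attribute.
#' @export
run_experiment <- function(name, config = list()) {
  drivers <- list(
    fwhm_vs_updates = exp_fwhm_vs_updates,
    fwhm_vs_contrast_size = exp_fwhm_vs_contrast_size,
    point_position_in_lesion = exp_point_position,
    rmse_psf_choice = exp_rmse_psf_choice,
    pvc_simple = exp_pvc_simple,
    pvc_torso = exp_pvc_torso,
    bladder_sensitivity = exp_bladder_sensitivity,
    ring_phantom = exp_ring_phantom)
  if (!name %in% names(drivers))
    stop("unknown experiment name: ", name)
  drivers[[name]](resolve_config(config))
}

exp_fwhm_vs_updates <- function(cfg) {
  positions <- cfg$positions %||% list(centre = c(0, 0, 0),
                                       offcentre = c(80, 0, 0))
  noise_conditions <- cfg$noise %||% c("noise_free", "noisy")
  seed <- cfg$seed %||% 1L
  out <- list()
  for (pn in names(positions)) {
    les <- lesion_spec(positions[[pn]], cfg$lesion_radius_mm %||% 36,
                       cfg$tbr %||% 10)
    scene <- simple_scene(cfg$grid, les)
    sim <- simulate_scene_sinogram(scene, cfg$orbit, cfg$collimator)
    for (nc in noise_conditions) {
      noise <- if (nc == "noisy")
        list(total_counts = cfg$total_counts,
             seed = derive_seed(seed, paste0("noise_", pn))) else NULL
      case <- run_perturbation_case(sim$sino, scene$mu, cfg$grid,
                                    positions[[pn]], cfg$collimator,
                                    cfg$settings, noise = noise)
      out[[paste(pn, nc)]] <- psf_rows(case$psf,
                                       list(position = pn, noise = nc))
    }
  }
  with_provenance(do.call(rbind, out), cfg, seed)
}

exp_fwhm_vs_contrast_size <- function(cfg) {
  centre <- cfg$position_mm %||% c(80, 0, 0)
  radii <- cfg$radii_mm %||% c(8, 12, 20, 28, 36)
  tbrs <- cfg$tbrs %||% c(5, 10, 25)
  cases <- unique(rbind(data.frame(radius = radii, tbr = 10),
                        data.frame(radius = 36, tbr = tbrs)))
  bg_cache <- NULL
  out <- list()
  for (i in seq_len(nrow(cases))) {
    les <- lesion_spec(centre, cases$radius[i], cases$tbr[i])
    scene <- simple_scene(cfg$grid, les)
    sim <- simulate_scene_sinogram(scene, cfg$orbit, cfg$collimator, bg_cache)
    bg_cache <- sim$background_sino
    case <- run_perturbation_case(sim$sino, scene$mu, cfg$grid, centre,
                                  cfg$collimator, cfg$settings)
    out[[i]] <- psf_rows(case$psf, list(radius_mm = cases$radius[i],
                                        tbr = cases$tbr[i]))
  }
  with_provenance(do.call(rbind, out), cfg)
}

exp_point_position <- function(cfg) {
  # the point stays at the isocentre; the lesion moves along +x so the
  # point sits at the centre, the edge voxel, or 2 voxels outside the edge
  r <- cfg$lesion_radius_mm %||% 36
  v <- cfg$grid$voxel_mm
  offsets <- list(centre = 0, edge = r - v / 2, outside = r + 2 * v)
  out <- list()
  for (on in names(offsets)) {
    les <- lesion_spec(c(offsets[[on]], 0, 0), r, cfg$tbr %||% 10)
    scene <- simple_scene(cfg$grid, les)
    sim <- simulate_scene_sinogram(scene, cfg$orbit, cfg$collimator)
    case <- run_perturbation_case(sim$sino, scene$mu, cfg$grid, c(0, 0, 0),
                                  cfg$collimator, cfg$settings)
    out[[on]] <- psf_rows(case$psf, list(point_in_lesion = on))
  }
  with_provenance(do.call(rbind, out), cfg)
}

exp_rmse_psf_choice <- function(cfg) {
  centre <- cfg$position_mm %||% c(80, 0, 0)
  les <- lesion_spec(centre, cfg$lesion_radius_mm %||% 36, cfg$tbr %||% 10)
  scene <- simple_scene(cfg$grid, les)
  sim <- simulate_scene_sinogram(scene, cfg$orbit, cfg$collimator)
  case <- run_perturbation_case(sim$sino, scene$mu, cfg$grid, centre,
                                cfg$collimator, cfg$settings)
  nonspec <- run_perturbation_case(sim$sino, scene$mu, cfg$grid, c(0, 0, 0),
                                   cfg$collimator, cfg$settings)
  fw <- max(case$psf[[length(case$psf)]]$fwhm_radial_mm, 10)
  region <- evaluation_region(scene$lesion_mask, cfg$grid, 2 * fw)
  rows <- lapply(names(case$base$images), function(u) {
    rec <- case$base$images[[u]]
    ref_cs <- convolve_with_psf(scene$activity,
                                psf_kernel(case$psf[[u]], cfg$grid))
    ref_ns <- convolve_with_psf(scene$activity,
                                psf_kernel(nonspec$psf[[u]], cfg$grid))
    data.frame(update = as.integer(u),
               rmse_case_specific = rmse_local(rec, ref_cs, region),
               rmse_non_specific = rmse_local(rec, ref_ns, region))
  })
  with_provenance(do.call(rbind, rows), cfg)
}

exp_pvc_simple <- function(cfg) {
  radii <- cfg$radii_mm %||% c(8, 12, 20, 28, 36)
  tbrs <- cfg$tbrs %||% c(5, 10, 25)
  positions <- cfg$positions %||% list(centre = c(0, 0, 0),
                                       offcentre = c(80, 0, 0))
  cases <- unique(rbind(expand.grid(radius = radii, tbr = 10),
                        expand.grid(radius = 36, tbr = tbrs)))
  out <- list()
  for (pn in names(positions)) {
    bg_cache <- NULL
    for (i in seq_len(nrow(cases))) {
      les <- lesion_spec(positions[[pn]], cases$radius[i], cases$tbr[i])
      scene <- simple_scene(cfg$grid, les)
      sim <- simulate_scene_sinogram(scene, cfg$orbit, cfg$collimator, bg_cache)
      bg_cache <- sim$background_sino
      case <- run_perturbation_case(sim$sino, scene$mu, cfg$grid,
                                    positions[[pn]], cfg$collimator,
                                    cfg$settings)
      pv <- pvc_over_series(case, scene$lesion_mask, scene$body_mask,
                            updates = cfg$pvc_updates)
      pv$position <- pn; pv$radius_mm <- cases$radius[i]
      pv$tbr <- cases$tbr[i]; pv$gt_rmv <- scene$gt_rmv
      pv$dev_uncorrected_pct <- percent_deviation(pv$rmv_uncorrected, scene$gt_rmv)
      pv$dev_corrected_pct <- percent_deviation(pv$rmv_corrected, scene$gt_rmv)
      out[[paste(pn, i)]] <- pv
    }
  }
  with_provenance(do.call(rbind, out), cfg)
}

exp_pvc_torso <- function(cfg) {
  orbit <- cfg$orbit_torso %||%
    orbit_spec("elliptical", semi_major_mm = 250, semi_minor_mm = 175,
               n_views = cfg$orbit$n_views)
  scenarios <- cfg$scenarios %||% list(
    list(scenario = "bone", lesions = "femoral", target = "femoral",
         total_counts = 5e6),
    list(scenario = "tektrotyd", lesions = "uniform4", target = "uniform4",
         total_counts = 22e6))
  seed <- cfg$seed %||% 1L
  out <- list()
  for (sc in scenarios) {
    noise <- if (isTRUE(sc$noisy))
      list(total_counts = sc$total_counts,
           seed = derive_seed(seed, paste0("torso_", sc$scenario))) else NULL
    res <- run_torso_case(sc$scenario, sc$lesions, sc$target, cfg$grid,
                          orbit, cfg$collimator, cfg$settings,
                          fine_factor = cfg$fine_factor %||% 2L,
                          bladder_multiplier = sc$bladder_multiplier %||% 15,
                          noise = noise, updates = cfg$pvc_updates)
    pv <- res$pvc
    pv$scenario <- sc$scenario; pv$lesion <- sc$target
    pv$noisy <- isTRUE(sc$noisy)
    out[[paste(sc$scenario, sc$target, isTRUE(sc$noisy))]] <- pv
  }
  with_provenance(do.call(rbind, out), cfg, seed)
}

exp_bladder_sensitivity <- function(cfg) {
  orbit <- cfg$orbit_torso %||%
    orbit_spec("elliptical", semi_major_mm = 250, semi_minor_mm = 175,
               n_views = cfg$orbit$n_views)
  out <- list()
  for (bm in cfg$bladder_multipliers %||% c(0, 15)) {
    scene <- make_torso_scene("bone", cfg$grid, lesions = "femoral",
                              bladder_multiplier = bm)
    sino <- forward_project(scene$activity, scene$attenuation, orbit,
                            cfg$collimator, "full")
    case <- run_perturbation_case(sino, scene$attenuation, cfg$grid,
                                  scene$lesion_centres$femoral,
                                  cfg$collimator, cfg$settings)
    out[[as.character(bm)]] <- psf_rows(case$psf,
                                        list(bladder_multiplier = bm))
  }
  with_provenance(do.call(rbind, out), cfg)
}

exp_ring_phantom <- function(cfg) {
  grid <- cfg$grid
  ring <- make_ring_cylinder(grid, length_mm = cfg$length_mm %||%
                               (if (grid$nz * grid$voxel_mm >= 216) 216 else 180))
  centre <- cfg$position_mm %||% c(110, 0, 0)
  les <- lesion_spec(centre, cfg$lesion_radius_mm %||% 12, cfg$tbr %||% 10)
  act <- add_lesion_into_ring(ring, les)
  mu <- make_attenuation_map(
    make_elliptical_cylinder(grid, 152, 108,
                             cfg$length_mm %||%
                               (if (grid$nz * grid$voxel_mm >= 216) 216 else 180)))
  sino <- forward_project(act, mu, cfg$orbit, cfg$collimator, "full")
  case <- run_perturbation_case(sino, mu, grid, centre, cfg$collimator,
                                cfg$settings)
  with_provenance(psf_rows(case$psf, list(phantom = "ring")), cfg)
}

# lesion inserted into the (possibly zero-valued) interior of a ring
add_lesion_into_ring <- function(ring, lesion) {
  m <- sphere_mask(ring$grid, lesion$centre_mm, lesion$radius_mm)
  v <- ring$values
  v[m] <- lesion$tbr * max(ring$values)
  volume_image(v, ring$grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
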