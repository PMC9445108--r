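# Digital phantom generation.  Voxelization is by voxel-centre inclusion
# (no anti-aliasing): a voxel belongs to a shape iff its centre satisfies
# the analytic inequality.  This keeps ground-truth regional means exact;
# digitisation can instead be reduced by generating on a finer grid and
# resampling (see resample_to_grid / block_average).

# logical mask of an axis-aligned ellipsoid (sphere if radii equal)
ellipsoid_mask <- function(grid, centre_mm, semi_mm) {
  ax <- grid_axes(grid)
  sx <- ((ax$x - centre_mm[1]) / semi_mm[1])^2
  sy <- ((ax$y - centre_mm[2]) / semi_mm[2])^2
  sz <- ((ax$z - centre_mm[3]) / semi_mm[3])^2
  xy <- outer(sx, sy, "+")
  arr <- array(FALSE, c(grid$nx, grid$ny, grid$nz))
  for (k in seq_len(grid$nz)) arr[, , k] <- xy + sz[k] <= 1
  arr
}

sphere_mask <- function(grid, centre_mm, radius_mm) {
  if (radius_mm <= 0) return(array(FALSE, c(grid$nx, grid$ny, grid$nz)))
  ellipsoid_mask(grid, centre_mm, rep(radius_mm, 3))
}

# elliptical cylinder along z, centred at centre_mm
ellcyl_mask <- function(grid, major_mm, minor_mm, length_mm,
                        centre_mm = c(0, 0, 0)) {
  ax <- grid_axes(grid)
  if (major_mm <= 0 || minor_mm <= 0 || length_mm <= 0)
    return(array(FALSE, c(grid$nx, grid$ny, grid$nz)))
  xy <- outer(((ax$x - centre_mm[1]) / major_mm)^2,
              ((ax$y - centre_mm[2]) / minor_mm)^2, "+") <= 1
  arr <- array(FALSE, c(grid$nx, grid$ny, grid$nz))
  zin <- abs(ax$z - centre_mm[3]) <= length_mm / 2
  for (k in which(zin)) arr[, , k] <- xy
  arr
}

# circular cylinder of radius r along z between z0 and z1
circcyl_mask <- function(grid, centre_xy_mm, radius_mm, z_range_mm) {
  ax <- grid_axes(grid)
  xy <- outer((ax$x - centre_xy_mm[1])^2, (ax$y - centre_xy_mm[2])^2, "+") <=
    radius_mm^2
  arr <- array(FALSE, c(grid$nx, grid$ny, grid$nz))
  zin <- ax$z >= z_range_mm[1] & ax$z <= z_range_mm[2]
  for (k in which(zin)) arr[, , k] <- xy
  arr
}

#' Uniform elliptical cylinder phantom
#'
#' Background phantom of the simple geometric scenes: a uniform elliptical
#' cylinder along the axial direction, centred at the isocentre.  Default
#' dimensions are major radius 152 mm, minor radius 108 mm, length 216 mm.
#'
#' @param grid a [grid_spec()].
#' @param major_mm,minor_mm transaxial semi-axes in mm (major along x).
#' @param length_mm axial length in mm.
#' @param value voxel value inside the cylinder.
#' @return a [volume_image()]; voxels whose centres satisfy
#'   `(x/major)^2 + (y/minor)^2 <= 1` and `|z| <= length/2` get `value`.
#' @export
make_elliptical_cylinder <- function(grid, major_mm = 152, minor_mm = 108,
                                     length_mm = 216, value = 1) {
  half <- c(grid$nx, grid$ny, grid$nz) * grid$voxel_mm / 2
  if (major_mm > half[1]) stop("cylinder exceeds the FOV along x (major axis)")
  if (minor_mm > half[2]) stop("cylinder exceeds the FOV along y (minor axis)")
  if (length_mm / 2 > half[3]) stop("cylinder exceeds the FOV along z (length)")
  m <- ellcyl_mask(grid, major_mm, minor_mm, length_mm)
  volume_image(m * value, grid)
}

#' Uniform ring (hollow cylinder) phantom
#'
#' The elliptical cylinder with its inner volume set to zero, used to study
#' the effect of the surrounding activity distribution on PSF convergence.
#'
#' @inheritParams make_elliptical_cylinder
#' @param wall_mm radial wall thickness of the ring in mm.
#' @return a [volume_image()].
#' @export
make_ring_cylinder <- function(grid, major_mm = 152, minor_mm = 108,
                               length_mm = 216, wall_mm = 30, value = 1) {
  outer_v <- make_elliptical_cylinder(grid, major_mm, minor_mm, length_mm, value)
  inner <- ellcyl_mask(grid, major_mm - wall_mm, minor_mm - wall_mm, length_mm)
  v <- outer_v$values
  v[inner] <- 0
  volume_image(v, grid)
}

#' Lesion specification
#'
#' @param centre_mm world position of the lesion centre (mm).
#' @param radius_mm sphere radius (mm); for `kind = "shell"` the outer
#'   radius.
#' @param tbr target-to-background ratio: ground-truth lesion voxel value is
#'   `tbr * background_value` (total, not additive).
#' @param kind `"uniform"` or `"shell"` (necrotic-core lesion: outer shell
#'   at `tbr`, inner core at `inner_tbr`).
#' @param inner_radius_mm core radius for shell lesions (< `radius_mm`).
#' @param inner_tbr core target-to-background ratio for shell lesions.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(centre_mm, radius_mm, tbr,
                        kind = c("uniform", "shell"),
                        inner_radius_mm = NULL, inner_tbr = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(centre_mm) == 3, radius_mm > 0, tbr > 0)
  if (kind == "shell") {
    stopifnot(!is.null(inner_radius_mm), !is.null(inner_tbr),
              inner_radius_mm > 0, inner_radius_mm < radius_mm, inner_tbr > 0)
  }
  structure(list(centre_mm = as.numeric(centre_mm),
                 radius_mm = radius_mm, tbr = tbr, kind = kind,
                 inner_radius_mm = inner_radius_mm, inner_tbr = inner_tbr),
            class = "lesion_spec")
}

#' Insert a lesion into a background volume
#'
#' Voxels whose centres fall inside the lesion sphere are set to
#' `tbr * background_value` (for shell lesions the core is set to
#' `inner_tbr * background_value`).  The lesion must lie entirely within the
#' background support.
#'
#' @param volume background [volume_image()].
#' @param lesion a [lesion_spec()].
#' @param background_value the background voxel value the TBR refers to.
#' @return a new [volume_image()].
#' @export
add_lesion <- function(volume, lesion, background_value) {
  stopifnot(inherits(lesion, "lesion_spec"), background_value > 0)
  m <- sphere_mask(volume$grid, lesion$centre_mm, lesion$radius_mm)
  if (!any(m)) stop("lesion contains no voxel centres")
  if (any(volume$values[m] <= 0))
    stop("lesion overlaps the background boundary")
  v <- volume$values
  v[m] <- lesion$tbr * background_value
  if (lesion$kind == "shell") {
    core <- sphere_mask(volume$grid, lesion$centre_mm, lesion$inner_radius_mm)
    v[core] <- lesion$inner_tbr * background_value
  }
  volume_image(v, volume$grid)
}

#' Lesion voxel mask
#'
#' The voxel-centre-inclusion mask of a lesion sphere -- the ground-truth
#' segmentation used as the STC target region.
#'
#' @inheritParams add_lesion
#' @param grid a [grid_spec()].
#' @return logical array.
#' @export
lesion_mask <- function(grid, lesion) {
  sphere_mask(grid, lesion$centre_mm, lesion$radius_mm)
}

#' Uniform attenuation map on the body support
#'
#' @param activity_support a [volume_image()]; voxels with positive value
#'   define the body support.
#' @param mu_per_mm linear attenuation coefficient in 1/mm (default 0.0154,
#'   water at 140 keV).
#' @return a [volume_image()] of mu values.
#' @export
make_attenuation_map <- function(activity_support, mu_per_mm = 0.0154) {
  if (mu_per_mm <= 0) stop("mu_per_mm must be > 0")
  volume_image((activity_support$values > 0) * mu_per_mm,
               activity_support$grid)
}

#' Single-voxel point source
#'
#' Activity in exactly one voxel: the voxel whose centre is nearest to
#' `position_mm` (boundary ties break toward the lower index).
#'
#' @param grid a [grid_spec()].
#' @param position_mm world position (mm), inside the FOV.
#' @param amplitude total activity of the point (value of the single voxel).
#' @return a [volume_image()] with `sum(values) == amplitude`.
#' @export
make_point_source <- function(grid, position_mm, amplitude = 1) {
  idx <- world_to_index(grid, position_mm)
  v <- array(0, c(grid$nx, grid$ny, grid$nz))
  v[idx[1], idx[2], idx[3]] <- amplitude
  volume_image(v, grid)
}

#' Geometric torso surrogate scenes
#'
#' Anthropomorphic activity/attenuation scenes built from geometric
#' primitives (elliptical body, ellipsoidal organs, cylindrical bone),
#' emulating a 99mTc phosphate bone scan of the pelvis and a 99mTc
#' EDDA/HYNIC-TOC (Tektrotyd) abdominal scan.  Organ shapes are synthetic
#' surrogates; only the lesion geometries, relative intensities and orbit
#' are scenario-defining:
#'
#' * `bone`: bone structures at intensity 1 over a small soft-tissue
#'   background (0.1), 15 mm diameter lesions at 5 x bone in the right
#'   iliac fossa and right femoral head, bladder at
#'   `bladder_multiplier` x bone (0 or 15).
#' * `tektrotyd`: liver at 1, spleen at 6.25/1.2 (so a 6.25 x liver lesion
#'   is 20% more intense than spleen), kidneys, bowel and bladder uptake;
#'   lesion menu: 30 mm uniform lesions at 4 x or 6.25 x liver, and a
#'   necrotic-core shell lesion (outer diameter 44.4 mm at 4 x liver,
#'   22 mm core at 1 x liver).
#'
#' @param scenario `"bone"` or `"tektrotyd"`.
#' @param grid a [grid_spec()].
#' @param lesions character vector selecting lesions: for `bone` any of
#'   `"iliac"`, `"femoral"`; for `tektrotyd` one of `"uniform4"`,
#'   `"uniform6.25"`, `"shell"`.
#' @param bladder_multiplier bone scenario bladder intensity as a multiple
#'   of bone (>= 0).
#' @param mu_per_mm uniform body attenuation coefficient (1/mm).
#' @param body_length_mm axial length of the body cylinder.
#' @return list with `activity` and `attenuation` [volume_image()]s,
#'   `lesion_masks` (named list of logical arrays), `lesion_values` (named
#'   ground-truth lesion RMVs), `lesion_centres` (named list), `body_mask`,
#'   and a `meta` list tagging organ intensities as surrogate defaults.
#' @export
make_torso_scene <- function(scenario = c("bone", "tektrotyd"), grid,
                             lesions = NULL, bladder_multiplier = 15,
                             mu_per_mm = 0.0154, body_length_mm = 184) {
  scenario <- match.arg(scenario)
  if (bladder_multiplier < 0) stop("bladder_multiplier must be >= 0")
  v <- array(0, c(grid$nx, grid$ny, grid$nz))
  body <- ellcyl_mask(grid, 150, 100, body_length_mm)
  lm <- list(); lv <- list(); lc <- list()
  if (scenario == "bone") {
    if (is.null(lesions)) lesions <- c("iliac", "femoral")
    bad <- setdiff(lesions, c("iliac", "femoral"))
    if (length(bad)) stop("unknown bone lesion tag: ", paste(bad, collapse = ", "))
    v[body] <- 0.1                                   # soft tissue
    bone_val <- 1
    sacrum <- circcyl_mask(grid, c(0, 30), 24, c(-20, 80))
    ili_r <- ellipsoid_mask(grid, c(60, 25, 30), c(42, 22, 34))
    ili_l <- ellipsoid_mask(grid, c(-60, 25, 30), c(42, 22, 34))
    fh_r <- sphere_mask(grid, c(70, 0, -40), 22)
    fh_l <- sphere_mask(grid, c(-70, 0, -40), 22)
    sh_r <- circcyl_mask(grid, c(74, 0), 13, c(-88, -40))
    sh_l <- circcyl_mask(grid, c(-74, 0), 13, c(-88, -40))
    for (m in list(sacrum, ili_r, ili_l, fh_r, fh_l, sh_r, sh_l))
      v[m & body] <- bone_val
    bl <- sphere_mask(grid, c(0, -40, -20), 28)
    v[bl & body] <- bladder_multiplier * bone_val
    if ("iliac" %in% lesions) {
      les <- lesion_spec(c(40, -5, 20), 7.5, 5)
      lm$iliac <- lesion_mask(grid, les) & body
      v[lm$iliac] <- 5 * bone_val
      lv$iliac <- 5 * bone_val; lc$iliac <- les$centre_mm
    }
    if ("femoral" %in% lesions) {
      les <- lesion_spec(c(70, 0, -40), 7.5, 5)
      lm$femoral <- lesion_mask(grid, les) & body
      v[lm$femoral] <- 5 * bone_val
      lv$femoral <- 5 * bone_val; lc$femoral <- les$centre_mm
    }
  } else {
    if (is.null(lesions)) lesions <- "uniform4"
    bad <- setdiff(lesions, c("uniform4", "uniform6.25", "shell"))
    if (length(bad)) stop("unknown tektrotyd lesion tag: ", paste(bad, collapse = ", "))
    liver_val <- 1; spleen_val <- 6.25 / 1.2
    v[body] <- 0.2                                   # soft tissue
    liver <- ellipsoid_mask(grid, c(60, 10, 25), c(70, 60, 55)) & body
    v[liver] <- liver_val
    spleen <- ellipsoid_mask(grid, c(-85, 25, 35), c(30, 25, 40)) & body
    v[spleen] <- spleen_val
    kid_r <- ellipsoid_mask(grid, c(55, 45, -30), c(20, 15, 28)) & body
    kid_l <- ellipsoid_mask(grid, c(-55, 45, -30), c(20, 15, 28)) & body
    v[kid_r] <- 2; v[kid_l] <- 2
    bowel <- ellipsoid_mask(grid, c(0, -25, -45), c(60, 40, 28)) & body
    v[bowel] <- 0.5
    bl <- sphere_mask(grid, c(0, -30, -62), 20) & body
    v[bl] <- 3
    centre <- c(60, 10, 25)                          # central in the liver
    if ("uniform4" %in% lesions) {
      les <- lesion_spec(centre, 15, 4)
      lm$uniform4 <- lesion_mask(grid, les)
      v[lm$uniform4] <- 4 * liver_val
      lv$uniform4 <- 4 * liver_val; lc$uniform4 <- centre
    }
    if ("uniform6.25" %in% lesions) {
      les <- lesion_spec(centre, 15, 6.25)
      lm$uniform6.25 <- lesion_mask(grid, les)
      v[lm$uniform6.25] <- 6.25 * liver_val
      lv$uniform6.25 <- 6.25 * liver_val; lc$uniform6.25 <- centre
    }
    if ("shell" %in% lesions) {
      les <- lesion_spec(centre, 22.2, 4, kind = "shell",
                         inner_radius_mm = 11, inner_tbr = 1)
      outer_m <- lesion_mask(grid, les)
      core_m <- sphere_mask(grid, centre, 11)
      v[outer_m] <- 4 * liver_val
      v[core_m] <- 1 * liver_val
      lm$shell <- outer_m
      lm$shell_core <- core_m
      n_out <- sum(outer_m & !core_m); n_core <- sum(core_m)
      lv$shell <- (4 * n_out + 1 * n_core) / (n_out + n_core) * liver_val
      lc$shell <- centre
    }
  }
  act <- volume_image(v, grid)
  list(activity = act,
       attenuation = make_attenuation_map(
         volume_image(body + 0, grid), mu_per_mm),
       lesion_masks = lm, lesion_values = lv, lesion_centres = lc,
       body_mask = body,
       meta = list(scenario = scenario, lesions = lesions,
                   bladder_multiplier = if (scenario == "bone") bladder_multiplier else NA,
                   organ_intensities = "synthetic surrogate defaults",
                   body_length_mm = body_length_mm, mu_per_mm = mu_per_mm))
}
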