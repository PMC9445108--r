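# File interchange: NIfTI and Interfile 3.3 for volumes, Interfile
# projection data (+ YAML provenance sidecar) for sinograms, YAML
# experiment configuration, and the deterministic fixture generator.
# Volumes are float64 in memory and float32 on disk.

#' Derive a named sub-seed from the run seed
#'
#' A single config seed fans out to named stage seeds so that adding a
#' stage never shifts the draws of existing stages.  The derivation is
#' `(seed * 1000003 + hash(stage) * 7919) mod 2147483629` (always below
#' 2^31).
#'
#' @param seed integer master seed.
#' @param stage character stage name (e.g. "noise", "fixtures").
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 2147483629 * 1000003 + h * 7919) %% 2147483629)
}

#' Write / read a volume
#'
#' NIfTI files carry the mm affine of the centred grid; Interfile files are
#' a 3.3 header (`.hv`) plus raw little-endian float32 (`.v`).  Values and
#' grid round-trip losslessly at float32 precision.
#'
#' @param vol a [volume_image()].
#' @param path output path (`.nii`/`.nii.gz` or `.hv`).
#' @param format `"nifti"` or `"interfile"`; inferred from the extension
#'   when missing.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  format <- format %||% infer_format(path)
  g <- vol$grid
  if (format == "nifti") {
    ax <- grid_axes(g)
    aff <- diag(c(g$voxel_mm, g$voxel_mm, g$voxel_mm, 1))
    aff[1:3, 4] <- c(ax$x[1], ax$y[1], ax$z[1])
    arr <- vol$values
    attr(arr, "pixdim") <- rep(g$voxel_mm, 3)
    img <- RNifti::asNifti(arr, datatype = "float")
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    write_interfile_volume(vol, path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    v <- array(as.numeric(img), dim(img))
    pix <- RNifti::pixdim(img)
    if (max(abs(pix - pix[1])) > 1e-6) stop("anisotropic NIfTI not supported")
    volume_image(pmax(v, 0), grid_spec(dim(v)[1], dim(v)[2], dim(v)[3], pix[1]))
  } else {
    read_interfile_volume(path)
  }
}

infer_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.h[vs]$", path)) "interfile"
  else stop("cannot infer format from path: ", path)
}

interfile_data_path <- function(path) sub("\\.h([vs])$", ".\\1", path)

write_interfile_volume <- function(vol, path) {
  g <- vol$grid
  dpath <- interfile_data_path(path)
  hdr <- c(
    "!INTERFILE :=",
    "!imaging modality := nucmed",
    "!version of keys := 3.3",
    paste0("name of data file := ", basename(dpath)),
    "!GENERAL IMAGE DATA :=",
    "!type of data := Tomographic",
    "imagedata byte order := LITTLEENDIAN",
    "!number format := short float",
    "!number of bytes per pixel := 4",
    "number of dimensions := 3",
    paste0("!matrix size [1] := ", g$nx),
    paste0("!matrix size [2] := ", g$ny),
    paste0("!matrix size [3] := ", g$nz),
    paste0("scaling factor (mm/pixel) [1] := ", format(g$voxel_mm)),
    paste0("scaling factor (mm/pixel) [2] := ", format(g$voxel_mm)),
    paste0("scaling factor (mm/pixel) [3] := ", format(g$voxel_mm)),
    "!END OF INTERFILE :=")
  writeLines(hdr, path)
  con <- file(dpath, "wb")
  on.exit(close(con))
  writeBin(as.vector(vol$values), con, size = 4, endian = "little")
  invisible(path)
}

parse_interfile_keys <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("INTERFILE", lines[1]))
    stop("malformed Interfile header (missing !INTERFILE marker): ", path)
  kv <- lines[grepl(":=", lines, fixed = TRUE)]
  keys <- tolower(trimws(gsub("^!|:=.*$", "", kv)))
  vals <- trimws(sub("^[^=]*:=", "", kv))
  setNames(vals, keys)
}

read_interfile_volume <- function(path) {
  keys <- parse_interfile_keys(path)
  need <- c("matrix size [1]", "matrix size [2]", "matrix size [3]",
            "scaling factor (mm/pixel) [1]")
  if (!all(need %in% names(keys)))
    stop("malformed Interfile header (missing matrix keys): ", path)
  d <- as.integer(keys[c("matrix size [1]", "matrix size [2]", "matrix size [3]")])
  vox <- as.numeric(keys["scaling factor (mm/pixel) [1]"])
  dpath <- file.path(dirname(path), keys[["name of data file"]])
  con <- file(dpath, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = prod(d), size = 4, endian = "little")
  if (length(v) != prod(d)) stop("Interfile data file truncated: ", dpath)
  volume_image(pmax(array(v, d), 0), grid_spec(d[1], d[2], d[3], vox))
}

#' Write / read a sinogram as Interfile projection data
#'
#' A 3.3 projection header (`.hs`) with the orbit keywords, raw
#' little-endian float32 counts (`.s`), and a YAML provenance sidecar
#' (`.yaml`).
#'
#' @param s a [sinogram()].
#' @param path output header path (`.hs`).
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(s, path) {
  stopifnot(grepl("\\.hs$", path))
  d <- dim(s$counts)
  dpath <- interfile_data_path(path)
  o <- s$orbit
  hdr <- c(
    "!INTERFILE :=",
    "!imaging modality := nucmed",
    "!version of keys := 3.3",
    paste0("name of data file := ", basename(dpath)),
    "!GENERAL DATA :=",
    "!type of data := PET",
    "imagedata byte order := LITTLEENDIAN",
    "!number format := short float",
    "!number of bytes per pixel := 4",
    paste0("!number of projections := ", o$n_views),
    paste0("!extent of rotation := ", format(o$arc_degrees)),
    paste0("orbit := ", o$kind),
    if (o$kind == "circular")
      paste0("radius := ", format(o$radius_mm))
    else c(paste0("semi major axis radius := ", format(o$semi_major_mm)),
           paste0("semi minor axis radius := ", format(o$semi_minor_mm))),
    paste0("!matrix size [1] := ", d[1]),
    paste0("!matrix size [2] := ", d[2]),
    paste0("scaling factor (mm/pixel) [1] := ", format(s$detector$bin_mm)),
    paste0("scaling factor (mm/pixel) [2] := ", format(s$detector$slice_mm)),
    "!END OF INTERFILE :=")
  writeLines(hdr, path)
  con <- file(dpath, "wb")
  on.exit(close(con))
  writeBin(as.vector(s$counts), con, size = 4, endian = "little")
  yaml::write_yaml(list(provenance = s$provenance),
                   sub("\\.hs$", ".yaml", path))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  keys <- parse_interfile_keys(path)
  need <- c("number of projections", "matrix size [1]", "matrix size [2]",
            "orbit")
  if (!all(need %in% names(keys)))
    stop("malformed Interfile projection header (missing keys): ", path)
  nv <- as.integer(keys["number of projections"])
  nb <- as.integer(keys["matrix size [1]"])
  ns <- as.integer(keys["matrix size [2]"])
  kind <- keys[["orbit"]]
  orbit <- if (kind == "circular") {
    orbit_spec("circular", radius_mm = as.numeric(keys["radius"]),
               n_views = nv, arc_degrees = as.numeric(keys["extent of rotation"]))
  } else {
    orbit_spec("elliptical",
               semi_major_mm = as.numeric(keys["semi major axis radius"]),
               semi_minor_mm = as.numeric(keys["semi minor axis radius"]),
               n_views = nv, arc_degrees = as.numeric(keys["extent of rotation"]))
  }
  det <- detector_spec(nb, as.numeric(keys["scaling factor (mm/pixel) [1]"]),
                       ns, as.numeric(keys["scaling factor (mm/pixel) [2]"]))
  dpath <- file.path(dirname(path), keys[["name of data file"]])
  con <- file(dpath, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = nb * ns * nv, size = 4, endian = "little")
  if (length(v) != nb * ns * nv) stop("Interfile data file truncated: ", dpath)
  prov <- list()
  side <- sub("\\.hs$", ".yaml", path)
  if (file.exists(side)) prov <- yaml::read_yaml(side)$provenance
  sinogram(pmax(array(v, c(nb, ns, nv)), 0), orbit, det, provenance = prov)
}

config_blocks <- c("scene", "geometry", "recon", "perturbation", "stc",
                   "evaluation", "seed", "scale")

#' Read and validate an experiment configuration
#'
#' YAML config with blocks `scene`, `geometry`, `recon`, `perturbation`,
#' `stc`, `evaluation` plus `seed` and `scale`; unknown top-level keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_blocks)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$seed) && (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed)))
    stop("seed must be an integer")
  if (!is.null(cfg$scale) && !cfg$scale %in% c("reduced", "full"))
    stop("scale must be 'reduced' or 'full'")
  cfg
}

#' Write the resolved configuration next to outputs
#' @param cfg config list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Deterministic miniature test assets
#'
#' Small fixtures generated in code: a 32^3 scene (cylinder + lesion) with
#' attenuation, its noise-free and noisy sinograms on a 20-view circular
#' orbit, a pre-blurred oracle volume (ground truth convolved with a known
#' isotropic kernel), and a synthetic separable Gaussian field with known
#' FWHMs for fit tests.  Identical seeds give identical fixtures.
#'
#' @param seed integer seed.
#' @return named list of fixture objects.
#' @export
make_fixtures <- function(seed = 1L) {
  grid <- grid_spec(32, 32, 32, 4)
  lesion <- lesion_spec(c(0, 0, 0), 16, 8)
  scene <- simple_scene(grid, lesion, major_mm = 52, minor_mm = 40,
                        length_mm = 100)
  orbit <- orbit_spec("circular", radius_mm = 100, n_views = 20)
  coll <- collimator_model(3.0, 0.045)
  sim <- simulate_scene_sinogram(scene, orbit, coll)
  noisy <- add_poisson_noise(scale_to_total_counts(sim$sino, 2e5),
                             derive_seed(seed, "fixtures"))
  psf <- structure(list(fwhm_radial_mm = 13.4, fwhm_tangential_mm = 9.2,
                        fwhm_axial_mm = 11.6, theta_deg = 0),
                   class = "psf_estimate")
  kern <- psf_kernel(psf, grid)
  blurred <- convolve_with_psf(scene$activity, kern)
  # centred on a voxel centre so fit planes sample the lattice exactly
  gauss <- synthetic_gaussian_field(grid, c(13.4, 9.2, 11.6),
                                    centre_mm = c(2, 2, 2))
  list(grid = grid, scene = scene, orbit = orbit, collimator = coll,
       sino = sim$sino, noisy_sino = noisy, psf = psf, kernel = kern,
       blurred = blurred, gaussian_field = gauss,
       gaussian_fwhm_mm = c(13.4, 9.2, 11.6),
       gaussian_centre_mm = c(2, 2, 2), seed = seed)
}

#' Synthetic separable Gaussian field with known FWHMs
#'
#' @param grid a [grid_spec()].
#' @param fwhm_mm length-3 FWHM along (x, y, z) in mm.
#' @param centre_mm field centre (default origin).
#' @param amplitude peak value.
#' @return a [difference_image()] (the natural input of the fit routines).
#' @export
synthetic_gaussian_field <- function(grid, fwhm_mm, centre_mm = c(0, 0, 0),
                                     amplitude = 1) {
  sg <- fwhm_mm / 2.354820045
  ax <- grid_axes(grid)
  gx <- exp(-(ax$x - centre_mm[1])^2 / (2 * sg[1]^2))
  gy <- exp(-(ax$y - centre_mm[2])^2 / (2 * sg[2]^2))
  gz <- exp(-(ax$z - centre_mm[3])^2 / (2 * sg[3]^2))
  difference_image(amplitude * outer(outer(gx, gy), gz), grid)
}
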