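#' Isotropic voxel grid specification
#'
#' Defines a 3D voxel grid with isotropic spacing and the world origin fixed
#' at the grid centre.  World coordinates are in mm, right-handed, with z the
#' axial direction.  The voxel centre of index `(i, j, k)` (1-based) sits at
#' `((i - (n+1)/2) * voxel_mm, ...)`; each voxel owns the half-open cube
#' `[centre - voxel/2, centre + voxel/2)`.
#'
#' @param nx,ny,nz voxel counts per axis (each >= 8; `nx == ny` is required
#'   by the rotation-based projector).
#' @param voxel_mm isotropic voxel edge length in mm (> 0).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(96, 96, 48, 4)
#' head(grid_axes(g)$x)
#' @export
grid_spec <- function(nx, ny = nx, nz, voxel_mm) {
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  if (any(c(nx, ny, nz) < 8L)) stop("grid dimensions must be >= 8")
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) stop("voxel_mm must be > 0")
  structure(list(nx = nx, ny = ny, nz = nz, voxel_mm = as.numeric(voxel_mm)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g mm (FOV %.0f x %.0f x %.0f mm)\n",
              x$nx, x$ny, x$nz, x$voxel_mm,
              x$nx * x$voxel_mm, x$ny * x$voxel_mm, x$nz * x$voxel_mm))
  invisible(x)
}

#' Voxel-centre world coordinates of each grid axis
#'
#' @param grid a [grid_spec()].
#' @return list with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates in mm.
#' @export
grid_axes <- function(grid) {
  ax <- function(n, v) ((seq_len(n)) - (n + 1) / 2) * v
  list(x = ax(grid$nx, grid$voxel_mm),
       y = ax(grid$ny, grid$voxel_mm),
       z = ax(grid$nz, grid$voxel_mm))
}

#' Convert a world position to the nearest voxel index
#'
#' Ties (positions exactly on a voxel boundary) break toward the lower
#' index, consistent with the half-open voxel convention.
#'
#' @param grid a [grid_spec()].
#' @param pos_mm numeric length-3 world position (mm).
#' @return integer length-3 1-based voxel index.
#' @export
world_to_index <- function(grid, pos_mm) {
  stopifnot(length(pos_mm) == 3)
  n <- c(grid$nx, grid$ny, grid$nz)
  f <- pos_mm / grid$voxel_mm + (n + 1) / 2
  # nearest centre; boundary (f - 0.5 integral) resolves to the lower voxel
  i <- as.integer(ceiling(f - 0.5))
  if (any(i < 1L) || any(i > n)) stop("position outside the grid FOV")
  i
}

#' Convert a voxel index to its centre world position
#' @param grid a [grid_spec()].
#' @param idx integer length-3 1-based voxel index.
#' @return numeric length-3 position in mm.
#' @export
index_to_world <- function(grid, idx) {
  n <- c(grid$nx, grid$ny, grid$nz)
  stopifnot(length(idx) == 3, all(idx >= 1), all(idx <= n))
  (idx - (n + 1) / 2) * grid$voxel_mm
}

#' Scalar volume on a voxel grid
#'
#' A non-negative, finite scalar field (activity in arbitrary units, or
#' attenuation coefficient mu per mm) bound to a [grid_spec()].
#'
#' @param values 3D numeric array with dim `c(nx, ny, nz)`.
#' @param grid a [grid_spec()].
#' @return An object of class `volume_image` with fields `values` and `grid`.
#' @export
volume_image <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!identical(dim(values), c(grid$nx, grid$ny, grid$nz)))
    stop("values dim does not match grid")
  if (any(!is.finite(values))) stop("volume values must be finite")
  if (any(values < 0)) stop("volume values must be non-negative")
  structure(list(values = values, grid = grid), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %d x %d x %d @ %.3g mm; range [%.4g, %.4g], total %.6g\n",
              x$grid$nx, x$grid$ny, x$grid$nz, x$grid$voxel_mm,
              min(x$values), max(x$values), sum(x$values)))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a$grid), unclass(b$grid)))
}

#' Regional mean value (RMV)
#'
#' Arithmetic mean of voxel values over a binary region mask -- the
#' quantification endpoint for lesions before and after partial volume
#' correction.
#'
#' @param img a [volume_image()].
#' @param mask logical array on the same grid (or a `volume_image` of 0/1).
#' @return scalar mean.
#' @export
regional_mean <- function(img, mask) {
  m <- as_mask(mask, img$grid)
  if (!any(m)) stop("empty region mask")
  mean(img$values[m])
}

as_mask <- function(mask, grid) {
  if (inherits(mask, "volume_image")) mask <- mask$values > 0
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), c(grid$nx, grid$ny, grid$nz)))
    stop("mask dim does not match grid")
  mask
}

#' Resample a volume onto another grid
#'
#' Trilinear interpolation of concentration values (not count-preserving)
#' between world-aligned grids sharing the centred-origin convention.
#' Positions outside the source FOV evaluate to 0.
#'
#' @param img a [volume_image()].
#' @param target_grid a [grid_spec()].
#' @return a [volume_image()] on `target_grid`.
#' @export
resample_to_grid <- function(img, target_grid) {
  if (isTRUE(all.equal(unclass(img$grid), unclass(target_grid))))
    return(img)
  src <- img$grid
  v <- img$values
  axs <- grid_axes(target_grid)
  # fractional source indices of every target voxel centre
  fx <- axs$x / src$voxel_mm + (src$nx + 1) / 2
  fy <- axs$y / src$voxel_mm + (src$ny + 1) / 2
  fz <- axs$z / src$voxel_mm + (src$nz + 1) / 2
  out <- trilinear_sample_grid(v, fx, fy, fz)
  if (inherits(img, "difference_image")) difference_image(out, target_grid)
  else volume_image(pmax(out, 0), target_grid)
}

# trilinear sample on a separable lattice of fractional indices
trilinear_sample_grid <- function(v, fx, fy, fz) {
  d <- dim(v)
  cl <- function(f, n) pmin(pmax(f, 1), n)
  ix0 <- floor(cl(fx, d[1])); ix0 <- pmin(ix0, d[1] - 1); wx <- cl(fx, d[1]) - ix0
  iy0 <- floor(cl(fy, d[2])); iy0 <- pmin(iy0, d[2] - 1); wy <- cl(fy, d[2]) - iy0
  iz0 <- floor(cl(fz, d[3])); iz0 <- pmin(iz0, d[3] - 1); wz <- cl(fz, d[3]) - iz0
  inx <- fx >= 0.5 & fx <= d[1] + 0.5
  iny <- fy >= 0.5 & fy <= d[2] + 0.5
  inz <- fz >= 0.5 & fz <= d[3] + 0.5
  nx <- length(fx); ny <- length(fy); nz <- length(fz)
  out <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    k0 <- iz0[k]; wzk <- wz[k]
    s00 <- v[, , k0]; s01 <- v[, , k0 + 1]
    sz <- s00 * (1 - wzk) + s01 * wzk
    # bilinear in (x, y) via indexing matrices
    m00 <- sz[cbind(rep(ix0, ny), rep(iy0, each = nx))]
    m10 <- sz[cbind(rep(ix0 + 1, ny), rep(iy0, each = nx))]
    m01 <- sz[cbind(rep(ix0, ny), rep(iy0 + 1, each = nx))]
    m11 <- sz[cbind(rep(ix0 + 1, ny), rep(iy0 + 1, each = nx))]
    wxm <- rep(wx, ny); wym <- rep(wy, each = nx)
    plane <- m00 * (1 - wxm) * (1 - wym) + m10 * wxm * (1 - wym) +
      m01 * (1 - wxm) * wym + m11 * wxm * wym
    plane[!(rep(inx, ny) & rep(iny, each = nx))] <- 0
    out[, , k] <- if (inz[k]) plane else 0
  }
  out
}

#' Block-average a volume onto a coarser grid
#'
#' Integer-factor block averaging (the adjoint-style complement of
#' [resample_to_grid()] used in round-trip checks).
#'
#' @param img a [volume_image()].
#' @param factor integer downsampling factor per axis.
#' @return a [volume_image()] with `dim/factor` voxels of size
#'   `voxel_mm * factor`.
#' @export
block_average <- function(img, factor) {
  factor <- as.integer(factor)
  d <- dim(img$values)
  if (any(d %% factor != 0)) stop("dims not divisible by factor")
  nd <- d %/% factor
  v <- img$values
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(v, c(2, 4, 6), mean)
  volume_image(out, grid_spec(nd[1], nd[2], nd[3], img$grid$voxel_mm * factor))
}
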