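# Single Target Correction (STC): iterative four-stage voxelwise partial
# volume correction of one target region and its background for spill-in
# and spill-out, driven by the case-specific anisotropic Gaussian PSF.

#' Region masks driving STC
#'
#' @param target logical array: the segmented lesion (non-empty).
#' @param body logical array: the body support.
#' @param background logical array; default the body support minus the
#'   target (whole-body background).
#' @return An object of class `region_masks`.
#' @export
region_masks <- function(target, body, background = NULL) {
  if (is.null(background)) background <- body & !target
  if (!any(target)) stop("target mask is empty")
  if (any(target & background)) stop("target and background masks overlap")
  if (any((target | background) & !body))
    stop("target/background must lie within the body support")
  structure(list(target = target, background = background, body = body),
            class = "region_masks")
}

#' STC settings
#'
#' @param n_iterations correction iterations (default 10, the published
#'   sufficiency default).
#' @param non_negativity clamp negative values to zero after each stage
#'   (default TRUE).
#' @param epsilon smallest admissible recovery-coefficient value inside a
#'   region; smaller values indicate kernel/mask inconsistency and raise an
#'   error.
#' @param scalar_rc stage-2 sensitivity variant: divide the whole target by
#'   the scalar mean recovery coefficient instead of voxelwise (default
#'   FALSE).
#' @return An object of class `stc_settings`.
#' @export
stc_settings <- function(n_iterations = 10L, non_negativity = TRUE,
                         epsilon = 1e-6, scalar_rc = FALSE) {
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(n_iterations = n_iterations,
                 non_negativity = isTRUE(non_negativity),
                 epsilon = epsilon, scalar_rc = isTRUE(scalar_rc)),
            class = "stc_settings")
}

#' Discretise a PSF estimate as a normalised 3D kernel
#'
#' Anisotropic Gaussian with (radial, tangential, axial) widths rotated
#' about the axial axis by the point azimuth, sampled on the voxel grid,
#' truncated at `truncation` sigma per axis and renormalised to unit mass.
#'
#' @param psf a PSF estimate from [estimate_psf()] (or any list with `fwhm_radial_mm`,
#'   `fwhm_tangential_mm`, `fwhm_axial_mm`, `theta_deg`).
#' @param grid the [grid_spec()] the kernel will act on.
#' @param truncation kernel truncation radius in sigma (default 4).
#' @return 3D array summing to 1, with attributes `sigma_mm`, `theta_deg`,
#'   and `undersampled` (TRUE if any FWHM < voxel/2).
#' @export
psf_kernel <- function(psf, grid, truncation = 4) {
  fw <- c(psf$fwhm_radial_mm, psf$fwhm_tangential_mm, psf$fwhm_axial_mm)
  if (any(!is.finite(fw)) || any(fw <= 0)) stop("PSF FWHMs must be > 0")
  sg <- fw / 2.354820045
  under <- any(fw < grid$voxel_mm / 2)
  if (under)
    warning("PSF FWHM below half the voxel size: kernel is undersampled")
  v <- grid$voxel_mm
  rxy <- ceiling(truncation * max(sg[1], sg[2]) / v)
  rz <- ceiling(truncation * sg[3] / v)
  if (2 * rxy + 1 > min(grid$nx, grid$ny) || 2 * rz + 1 > grid$nz)
    stop("kernel does not fit in the grid")
  th <- psf$theta_deg * pi / 180
  xo <- (-rxy:rxy) * v
  zo <- (-rz:rz) * v
  nxk <- length(xo)
  x2 <- matrix(xo, nxk, nxk)
  y2 <- matrix(xo, nxk, nxk, byrow = TRUE)
  r <- x2 * cos(th) + y2 * sin(th)
  t <- -x2 * sin(th) + y2 * cos(th)
  k2 <- exp(-r^2 / (2 * sg[1]^2) - t^2 / (2 * sg[2]^2))
  kz <- exp(-zo^2 / (2 * sg[3]^2))
  k <- outer(k2, kz)
  k <- k / sum(k)
  attr(k, "sigma_mm") <- sg
  attr(k, "theta_deg") <- psf$theta_deg
  attr(k, "undersampled") <- under
  # separable factors for the direct convolution path
  attr(k, "k2") <- k2 / sum(k2)
  attr(k, "kz") <- kz / sum(kz)
  aligned <- abs(sin(th)) < 1e-12 || abs(cos(th)) < 1e-12 ||
    abs(sg[1] - sg[2]) < 1e-12
  if (aligned) {
    swap <- abs(cos(th)) < 1e-12 && abs(sg[1] - sg[2]) >= 1e-12
    sx <- if (swap) sg[2] else sg[1]
    sy <- if (swap) sg[1] else sg[2]
    gx <- exp(-xo^2 / (2 * sx^2))
    gy <- exp(-xo^2 / (2 * sy^2))
    attr(k, "kx") <- gx / sum(gx)
    attr(k, "ky") <- gy / sum(gy)
  }
  k
}

# dispatch: fast separable C++ path when the kernel carries its factors,
# generic FFT otherwise
conv_kernel <- function(vol, kernel) {
  kz <- attr(kernel, "kz")
  if (is.null(kz)) return(fft_convolve3(vol, kernel))
  kx <- attr(kernel, "kx") %||% numeric(0)
  ky <- attr(kernel, "ky") %||% numeric(0)
  cpp_convolve_k2z(vol, attr(kernel, "k2"), kz, kx, ky)
}

next_fast_len <- function(n) {
  repeat {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# padded FFT convolution of a 3D array with a (smaller, odd-dim) kernel
fft_convolve3 <- function(vol, kernel) {
  dv <- dim(vol); dk <- dim(kernel)
  dp <- vapply(dv + dk - 1, next_fast_len, numeric(1))
  pv <- array(0, dp); pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kernel
  out <- Re(fft(fft(pv) * fft(pk), inverse = TRUE)) / prod(dp)
  off <- (dk - 1) / 2
  out[off[1] + seq_len(dv[1]), off[2] + seq_len(dv[2]), off[3] + seq_len(dv[3])]
}

#' Convolve a volume with a PSF kernel
#'
#' Padded (non-circular) convolution; mass is preserved away from the
#' volume edges since the kernel is normalised.  Used both by the STC
#' smoothing operator and to build the blurred-ground-truth reference of
#' the RMSE assessment.
#'
#' @param gt a [volume_image()] (or [difference_image()]).
#' @param kernel a [psf_kernel()] (any normalised 3D array).
#' @return an object of the same class as `gt`.
#' @export
convolve_with_psf <- function(gt, kernel) {
  if (any(dim(kernel) > dim(gt$values))) stop("kernel larger than the volume")
  out <- conv_kernel(gt$values, kernel)
  if (inherits(gt, "volume_image")) volume_image(pmax(out, 0), gt$grid)
  else difference_image(out, gt$grid)
}

#' Single Target Correction
#'
#' Iterative four-stage voxelwise PVC with smoothing operator `H`
#' (convolution by `kernel`), target/background indicators `m_T`, `m_B`,
#' and `b_0 = f`:
#' 1. target spill-in:   `s_T = f - H(b * m_B)`;
#' 2. target spill-out:  `t(v) = s_T(v) / [H m_T](v)` on target voxels
#'    (voxelwise recovery coefficient, uniform-target assumption);
#' 3. background spill-in: `s_B = f - H(t * m_T)`;
#' 4. background spill-out: `b(v) = s_B(v) / [H m_B](v)` on background
#'    voxels;
#' with negatives clamped after each stage when non-negativity is on.  The
#' corrected image is `t * m_T + b * m_B`.
#'
#' @param f observed [volume_image()] (the reconstruction).
#' @param masks a [region_masks()] on `f`'s grid.
#' @param kernel a [psf_kernel()].
#' @param settings an [stc_settings()].
#' @return An object of class `correction_result`: `corrected`
#'   ([volume_image()]), `rmv_trace` (target RMV per iteration), `settings`
#'   and kernel attributes as provenance.
#' @export
stc_correct <- function(f, masks, kernel, settings = stc_settings()) {
  g <- f$grid
  mT <- as_mask(masks$target, g)
  mB <- as_mask(masks$background, g)
  if (abs(sum(kernel) - 1) > 1e-6) stop("kernel must be normalised")
  HmT <- conv_kernel(mT * 1.0, kernel)
  HmB <- conv_kernel(mB * 1.0, kernel)
  eps <- settings$epsilon
  if (any(HmT[mT] < eps)) {
    v <- which(mT & array(HmT < eps, dim(HmT)))[1]
    stop("recovery coefficient below epsilon at target voxel ", v,
         " (kernel/mask inconsistency)")
  }
  if (any(HmB[mB] < eps)) {
    v <- which(mB & array(HmB < eps, dim(HmB)))[1]
    stop("recovery coefficient below epsilon at background voxel ", v,
         " (kernel/mask inconsistency)")
  }
  clamp <- function(x) if (settings$non_negativity) pmax(x, 0) else x
  fv <- f$values
  b <- fv
  t_img <- array(0, dim(fv))
  trace <- numeric(settings$n_iterations)
  for (k in seq_len(settings$n_iterations)) {
    sT <- clamp(fv - conv_kernel(b * mB, kernel))           # stage 1
    t_img <- array(0, dim(fv))                                 # stage 2
    if (settings$scalar_rc) {
      t_img[mT] <- sT[mT] / mean(HmT[mT])
    } else {
      t_img[mT] <- sT[mT] / HmT[mT]
    }
    t_img <- clamp(t_img)
    sB <- clamp(fv - conv_kernel(t_img * mT, kernel))       # stage 3
    b <- array(0, dim(fv))                                     # stage 4
    b[mB] <- sB[mB] / HmB[mB]
    b <- clamp(b)
    trace[k] <- mean(t_img[mT])
  }
  corrected <- array(0, dim(fv))
  corrected[mT] <- t_img[mT]
  corrected[mB] <- b[mB]
  # the returned image is physical activity: clamp the final container even
  # when intermediate non-negativity is disabled
  structure(list(corrected = volume_image(pmax(corrected, 0), g),
                 rmv_trace = trace, settings = settings,
                 kernel_sigma_mm = attr(kernel, "sigma_mm"),
                 kernel_theta_deg = attr(kernel, "theta_deg")),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("<correction_result> %d STC iterations; target RMV %.5g\n",
              length(x$rmv_trace), tail(x$rmv_trace, 1)))
  invisible(x)
}
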