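delta_kernel <- function() {
  k <- array(1, c(1, 1, 1))
  attr(k, "k2") <- matrix(1, 1, 1)
  attr(k, "kz") <- 1
  attr(k, "sigma_mm") <- c(0, 0, 0)
  attr(k, "theta_deg") <- 0
  k
}

test_that("PSF kernels are normalised, symmetric when isotropic, and flat-field neutral", {
  g <- grid_spec(64, 64, 32, 4)
  iso <- structure(list(fwhm_radial_mm = 12, fwhm_tangential_mm = 12,
                        fwhm_axial_mm = 12, theta_deg = 30),
                   class = "psf_estimate")
  k <- psf_kernel(iso, g)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # isotropic kernel is invariant under a 90-degree axial rotation
  rot <- aperm(k, c(2, 1, 3))[rev(seq_len(dim(k)[1])), , , drop = FALSE]
  expect_lt(max(abs(k - rot)), 1e-6)
  # convolving a wide uniform slab leaves its interior unchanged
  slab <- array(0, c(64, 64, 32)); slab[10:55, 10:55, 5:28] <- 2
  out <- pertspect:::conv_kernel(slab, k)
  expect_lt(max(abs(out[25:40, 25:40, 14:19] - 2)), 1e-4)
  expect_warning(psf_kernel(structure(list(fwhm_radial_mm = 1,
                                           fwhm_tangential_mm = 12,
                                           fwhm_axial_mm = 12, theta_deg = 0),
                                      class = "psf_estimate"), g),
                 "undersampled")
  tiny <- grid_spec(8, 8, 8, 1)
  expect_error(psf_kernel(iso, tiny), "fit in the grid")
})

test_that("separable C++ convolution agrees with the FFT reference", {
  g <- grid_spec(24, 24, 16, 4)
  set.seed(7)
  v <- array(runif(24 * 24 * 16), c(24, 24, 16))
  for (th in c(0, 9.5, 45, 90)) {
    psf <- structure(list(fwhm_radial_mm = 13, fwhm_tangential_mm = 9,
                          fwhm_axial_mm = 11, theta_deg = th),
                     class = "psf_estimate")
    k <- psf_kernel(psf, g)
    a <- pertspect:::conv_kernel(v, k)
    b <- pertspect:::fft_convolve3(v, array(as.numeric(k), dim(k)))
    expect_lt(max(abs(a - b)), 1e-12)
  }
})

test_that("STC with a delta kernel returns the input on target and background", {
  fx <- fixtures()
  f <- fx$scene$activity
  masks <- region_masks(fx$scene$lesion_mask, fx$scene$body_mask)
  res <- stc_correct(f, masks, delta_kernel())
  inb <- masks$target | masks$background
  expect_identical(res$corrected$values[inb], f$values[inb])
})

test_that("STC recovers the ground truth on the convolution oracle", {
  fx <- fixtures()
  masks <- region_masks(fx$scene$lesion_mask, fx$scene$body_mask)
  res <- stc_correct(fx$blurred, masks, fx$kernel)
  gt <- fx$scene$gt_rmv
  corrected <- regional_mean(res$corrected, masks$target)
  expect_equal(corrected, gt, tolerance = 0.01)
  expect_length(res$rmv_trace, 10)
  # the error trace is non-increasing after the second iteration
  err <- abs(res$rmv_trace - gt)
  expect_true(all(diff(err[-1]) <= 1e-9))
  # deterministic: identical inputs give bit-identical output
  res2 <- stc_correct(fx$blurred, masks, fx$kernel)
  expect_identical(res$corrected$values, res2$corrected$values)
})

test_that("STC reduces the RMV error for every lesion radius in the size menu", {
  g <- grid_spec(96, 96, 48, 4)
  psf <- structure(list(fwhm_radial_mm = 14, fwhm_tangential_mm = 14,
                        fwhm_axial_mm = 14, theta_deg = 0),
                   class = "psf_estimate")
  kern <- psf_kernel(psf, g)
  for (r in c(8, 12, 20, 28, 36)) {
    les <- lesion_spec(c(0, 0, 0), r, 10)
    scene <- simple_scene(g, les)
    blurred <- convolve_with_psf(scene$activity, kern)
    masks <- region_masks(scene$lesion_mask, scene$body_mask)
    res <- stc_correct(blurred, masks, kern)
    err_unc <- abs(regional_mean(blurred, masks$target) - 10)
    err_cor <- abs(regional_mean(res$corrected, masks$target) - 10)
    expect_lt(err_cor, err_unc)
  }
})

test_that("STC preserves heterogeneity: corrected core stays below the shell", {
  g <- grid_spec(96, 96, 48, 4)
  bg <- make_elliptical_cylinder(g, 100, 72, 180, 1)
  les <- lesion_spec(c(0, 0, 0), 22.2, 4, kind = "shell",
                     inner_radius_mm = 11, inner_tbr = 1)
  act <- add_lesion(bg, les, 1)
  psf <- structure(list(fwhm_radial_mm = 11, fwhm_tangential_mm = 11,
                        fwhm_axial_mm = 11, theta_deg = 0),
                   class = "psf_estimate")
  kern <- psf_kernel(psf, g)
  blurred <- convolve_with_psf(act, kern)
  whole <- lesion_mask(g, les)
  masks <- region_masks(whole, bg$values > 0)
  res <- stc_correct(blurred, masks, kern)
  core <- pertspect:::sphere_mask(g, c(0, 0, 0), 11)
  expect_lt(mean(res$corrected$values[core]),
            mean(res$corrected$values[whole & !core]))
})

test_that("local STC matches whole-body STC on the target RMV", {
  fx <- fixtures()
  masks <- region_masks(fx$scene$lesion_mask, fx$scene$body_mask)
  full <- stc_correct(fx$blurred, masks, fx$kernel)
  loc <- stc_correct_local(fx$blurred, fx$scene$lesion_mask,
                           fx$scene$body_mask, fx$kernel, margin_mm = 48)
  sub <- function(a) a[loc$crop$lo[1]:loc$crop$hi[1],
                       loc$crop$lo[2]:loc$crop$hi[2],
                       loc$crop$lo[3]:loc$crop$hi[3]]
  tm <- sub(fx$scene$lesion_mask)
  expect_equal(mean(loc$corrected$values[tm]),
               regional_mean(full$corrected, fx$scene$lesion_mask),
               tolerance = 5e-4)
})

test_that("mask invariants are enforced", {
  fx <- fixtures()
  t <- fx$scene$lesion_mask
  b <- fx$scene$body_mask
  expect_error(region_masks(t, b, background = t), "overlap")
  expect_error(region_masks(array(FALSE, dim(t)), b), "empty")
  out <- !t   # includes everything outside the body support
  expect_error(region_masks(t, b, background = out), "body support")
  expect_error(stc_settings(0), "n_iterations")
  expect_error(stc_settings(10, epsilon = 0), "epsilon")
  badk <- array(1, c(3, 3, 3))
  expect_error(stc_correct(fx$blurred, region_masks(t, b), badk),
               "normalised")
})

test_that("the scalar recovery-coefficient variant runs and differs from voxelwise", {
  fx <- fixtures()
  masks <- region_masks(fx$scene$lesion_mask, fx$scene$body_mask)
  vox <- stc_correct(fx$blurred, masks, fx$kernel)
  sca <- stc_correct(fx$blurred, masks, fx$kernel,
                     stc_settings(scalar_rc = TRUE))
  expect_false(identical(vox$corrected$values, sca$corrected$values))
  expect_equal(regional_mean(sca$corrected, masks$target),
               fx$scene$gt_rmv, tolerance = 0.05)
})

test_that("disabling intermediate non-negativity still yields a physical image", {
  fx <- fixtures()
  masks <- region_masks(fx$scene$lesion_mask, fx$scene$body_mask)
  res <- stc_correct(fx$blurred, masks, fx$kernel,
                     stc_settings(non_negativity = FALSE))
  expect_true(all(res$corrected$values >= 0))
  expect_equal(regional_mean(res$corrected, masks$target), fx$scene$gt_rmv,
               tolerance = 0.01)
})
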