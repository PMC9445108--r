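test_that("plane fits recover a noiseless sampled Gaussian within 1%", {
  fx <- fixtures()
  field <- fx$gaussian_field
  est <- estimate_psf(field, fx$gaussian_centre_mm, fit_config(theta_deg = 0))
  expect_equal(est$fwhm_radial_mm, 13.4, tolerance = 0.01)
  expect_equal(est$fwhm_tangential_mm, 9.2, tolerance = 0.01)
  expect_equal(est$fwhm_axial_mm, 11.6, tolerance = 0.01)
  expect_true(est$valid)
  # two-plane averaging is the exact arithmetic mean of the plane values
  expect_equal(est$fwhm_radial_mm,
               mean(c(est$planes$transaxial$fwhm_u,
                      est$planes$radial_axial$fwhm_u)))
  expect_equal(est$fwhm_axial_mm,
               mean(c(est$planes$radial_axial$fwhm_v,
                      est$planes$tangential_axial$fwhm_v)))
})

test_that("isotropic fields give equal widths; theta 0 maps radial to x", {
  g <- grid_spec(32, 32, 32, 4)
  iso <- synthetic_gaussian_field(g, c(12, 12, 12), centre_mm = c(2, 2, 2))
  f <- fit_plane_gaussian(iso, "transaxial", c(2, 2, 2),
                          fit_config(theta_deg = 0))
  expect_equal(f$fwhm_u, f$fwhm_v, tolerance = 1e-6)
  aniso <- synthetic_gaussian_field(g, c(14, 9, 11), centre_mm = c(2, 2, 2))
  est <- estimate_psf(aniso, c(2, 2, 2), fit_config(theta_deg = 0))
  expect_equal(est$theta_deg, 0)
  expect_equal(est$fwhm_radial_mm, 14, tolerance = 0.01)  # radial == x
})

test_that("fits under 5% noise recover truth within 3 SDs across seeds", {
  g <- grid_spec(32, 32, 32, 4)
  truth <- c(12, 8, 10)
  clean <- synthetic_gaussian_field(g, truth, centre_mm = c(2, 2, 2))
  hits <- 0L; n <- 100L
  for (s in seq_len(n)) {
    set.seed(1000 + s)
    noisy <- difference_image(
      clean$values + rnorm(length(clean$values), sd = 0.05), g)
    f <- fit_plane_gaussian(noisy, "transaxial", c(2, 2, 2),
                            fit_config(theta_deg = 0))
    if (abs(f$fwhm_u - 12) <= 3 * f$sd_u) hits <- hits + 1L
  }
  # ~99.7% coverage nominally; allow a modest shortfall
  expect_gte(hits, 90L)
})

test_that("fit region must fit inside the volume; failures are flagged not NaN", {
  g <- grid_spec(32, 32, 32, 4)
  field <- synthetic_gaussian_field(g, c(12, 12, 12))
  expect_error(fit_plane_gaussian(field, "transaxial", c(58, 0, 0),
                                  fit_config(theta_deg = 0)), "edge")
  flat <- difference_image(array(0, c(32, 32, 32)), g)
  f <- fit_plane_gaussian(flat, "transaxial", c(2, 2, 2),
                          fit_config(theta_deg = 0))
  expect_true(is.list(f))   # degenerate fit returns a record, never crashes
  expect_error(fit_config(half_width_vox = 2), ">= 3")
})

test_that("perturbation difference of a zero point source is exactly zero", {
  mini <- mini_case_central()
  set <- mini_settings(checkpoints = c(50, 100))
  point_sino <- forward_project(
    make_point_source(mini_grid(), c(-2, -2, -2), 1), mini$scene$mu,
    mini_orbit(), collimator_model(), "full")
  pd <- perturb_and_difference(mini$sim$sino, point_sino, 0, mini$scene$mu,
                               mini_grid(), set)
  expect_identical(max(abs(pd$diff[["100"]]$values)), 0)
  # paired reconstructions must share settings
  other <- osem_reconstruct(mini$sim$sino, mini$scene$mu, mini_grid(),
                            mini_settings(checkpoints = c(100, 200)))
  expect_error(perturb_and_difference(mini$sim$sino, point_sino, 1,
                                      mini$scene$mu, mini_grid(), set,
                                      base_series = other), "settings")
})

test_that("calibration hits the published contrast window and scales near-linearly", {
  mini <- mini_case_central()
  case <- mini$case
  expect_gt(case$contrast, 0.02)
  expect_lte(case$contrast, 0.10)
  final <- as.character(max(as.integer(names(case$psf))))
  expect_true(case$psf[[final]]$valid)
  # halving the scale roughly halves the achieved contrast
  set <- recon_settings(10L, 20L, checkpoints = 200L)
  point_sino <- forward_project(
    make_point_source(mini_grid(), case$point_mm, 1), mini$scene$mu,
    mini_orbit(), collimator_model(), "full")
  pd <- perturb_and_difference(mini$sim$sino, point_sino, case$scale / 2,
                               mini$scene$mu, mini_grid(), set)
  idx <- world_to_index(mini_grid(), case$point_mm)
  bv <- pd$base$images[["200"]]$values[idx[1], idx[2], idx[3]]
  reg <- pd$diff[["200"]]$values[(idx[1] - 3):(idx[1] + 3),
                                 (idx[2] - 3):(idx[2] + 3),
                                 (idx[3] - 3):(idx[3] + 3)]
  half_contrast <- max(reg) / bv
  expect_equal(half_contrast, case$contrast / 2,
               tolerance = 0.2 * case$contrast / 2)
})

test_that("a perturbation point in zero-activity air is rejected", {
  mini <- mini_case_central()
  set <- mini$case$base$settings
  point_air <- c(-120, 0, 0)   # outside the phantom, inside the FOV
  point_sino <- forward_project(
    make_point_source(mini_grid(), point_air, 1), mini$scene$mu,
    mini_orbit(), collimator_model(), "full")
  expect_error(
    calibrate_point_scale(point_sino, mini$sim$sino, mini$case$base,
                          mini$scene$mu, mini_grid(), set, point_air),
    "zero activity")
})

test_that("difference image integrates to the reconstructed point mass", {
  mini <- mini_case_central()
  d <- mini$case$diff[["200"]]
  mass <- sum(d$values) * mini_grid()$voxel_mm^3
  expect_true(is.finite(mass) && mass > 0)
  # the point's ground-truth mass is scale * voxel volume
  expect_equal(mass, mini$case$scale * mini_grid()$voxel_mm^3,
               tolerance = 0.5)
})
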