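test_that("local RMSE matches hand-computed and brute-force values", {
  g <- grid_spec(8, 8, 8, 1)
  r <- array(0, c(8, 8, 8)); cc <- array(0, c(8, 8, 8))
  m <- array(FALSE, c(8, 8, 8))
  r[1:3, 1, 1] <- c(1, 2, 3); cc[1:3, 1, 1] <- c(1, 2, 5)
  m[1:3, 1, 1] <- TRUE
  R <- volume_image(r, g); C <- volume_image(cc, g)
  expect_equal(rmse_local(R, C, m), sqrt(4 / 3))
  expect_equal(rmse_local(R, R, m), 0)
  expect_error(rmse_local(R, C, array(FALSE, c(8, 8, 8))), "empty")
  # random regions against an independent direct-sum oracle at 1e-12
  set.seed(42)
  for (i in 1:5) {
    rv <- array(runif(512), c(8, 8, 8))
    cv <- array(runif(512), c(8, 8, 8))
    mm <- array(runif(512) < 0.3, c(8, 8, 8))
    if (!any(mm)) next
    acc <- 0; n <- 0
    for (ii in 1:8) for (jj in 1:8) for (kk in 1:8) {
      if (mm[ii, jj, kk]) { acc <- acc + (rv[ii, jj, kk] - cv[ii, jj, kk])^2; n <- n + 1 }
    }
    expect_equal(rmse_local(volume_image(rv, g), volume_image(cv, g), mm),
                 sqrt(acc / n), tolerance = 1e-12)
  }
})

test_that("percent deviation follows its definition", {
  expect_equal(percent_deviation(9, 10), -10)
  expect_equal(percent_deviation(10, 10), 0)
  expect_equal(percent_deviation(13, 10), 30)
  expect_error(percent_deviation(1, 0), "non-zero")
})

test_that("convolution against a brute-force direct sum on a small crop", {
  g <- grid_spec(16, 16, 16, 4)
  set.seed(5)
  v <- array(runif(16^3), c(16, 16, 16))
  psf <- structure(list(fwhm_radial_mm = 10, fwhm_tangential_mm = 8,
                        fwhm_axial_mm = 9, theta_deg = 0),
                   class = "psf_estimate")
  k <- psf_kernel(psf, g)
  out <- pertspect:::conv_kernel(v, k)
  dk <- dim(k); off <- (dk - 1) / 2
  brute <- function(i, j, l) {
    acc <- 0
    for (a in seq_len(dk[1])) for (b in seq_len(dk[2])) for (d in seq_len(dk[3])) {
      ii <- i - (a - 1 - off[1]); jj <- j - (b - 1 - off[2]); ll <- l - (d - 1 - off[3])
      if (ii >= 1 && ii <= 16 && jj >= 1 && jj <= 16 && ll >= 1 && ll <= 16)
        acc <- acc + v[ii, jj, ll] * k[a, b, d]
    }
    acc
  }
  for (pt in list(c(8, 8, 8), c(3, 12, 6), c(14, 2, 15))) {
    expect_equal(out[pt[1], pt[2], pt[3]], brute(pt[1], pt[2], pt[3]),
                 tolerance = 1e-10)
  }
  # mass is preserved for interior-supported activity
  v2 <- array(0, c(16, 16, 16)); v2[6:11, 6:11, 6:11] <- v[6:11, 6:11, 6:11]
  blurred <- convolve_with_psf(volume_image(v2, g), k)
  expect_equal(sum(blurred$values), sum(v2), tolerance = 1e-6)
})

test_that("evaluation regions contain and dilate the lesion", {
  g <- grid_spec(48, 48, 24, 4)
  m <- pertspect:::sphere_mask(g, c(0, 0, 0), 16)
  reg <- evaluation_region(m, g, 12)
  expect_true(all(reg$mask[m]))
  expect_gt(reg$N, sum(m))
  expect_equal(reg$N, sum(pertspect:::sphere_mask(g, c(0, 0, 0), 28)),
               tolerance = 0.15)
})

test_that("experiment dispatch validates names and emits provenance-tagged tables", {
  expect_error(run_experiment("no_such_thing"), "unknown experiment")
  cfg <- list(grid = grid_spec(80, 80, 48, 4),
              orbit = orbit_spec("circular", radius_mm = 260, n_views = 20),
              settings = recon_settings(4L, 5L, checkpoints = c(10, 20)),
              positions = list(centre = c(0, 0, 0)),
              noise = "noise_free", lesion_radius_mm = 36, tbr = 10)
  df <- run_experiment("fwhm_vs_updates", cfg)
  expect_s3_class(df, "data.frame")
  expect_true(all(c("update", "fwhm_radial_mm", "fwhm_tangential_mm",
                    "fwhm_axial_mm", "contrast", "position", "noise") %in%
                    names(df)))
  expect_equal(sort(unique(df$update)), c(10, 20))
  prov <- attr(df, "provenance")
  expect_equal(prov$orbit$n_views, 20)
  expect_equal(prov$settings$n_subsets, 4)
})
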