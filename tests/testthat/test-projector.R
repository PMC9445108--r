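test_that("projection is linear: zero in, zero out; combine commutes with project", {
  fx <- fixtures()
  g <- fx$grid
  zero <- volume_image(array(0, c(32, 32, 32)), g)
  s0 <- forward_project(zero, fx$scene$mu, fx$orbit, fx$collimator, "full")
  expect_equal(sum(s0$counts), 0)

  a <- fx$scene$background
  b <- fx$scene$lesion_indicator
  mu <- fx$scene$mu
  sa <- forward_project(a, mu, fx$orbit, fx$collimator, "full")
  sb <- forward_project(b, mu, fx$orbit, fx$collimator, "full")
  mixed <- volume_image(2 * a$values + 3 * b$values, g)
  sm <- forward_project(mixed, mu, fx$orbit, fx$collimator, "full")
  comb <- combine_sinograms(list(list(sa, 2), list(sb, 3)))
  expect_lt(max(abs(sm$counts - comb$counts)) / max(sm$counts), 1e-9)
  # scale 0 leaves the other component untouched
  expect_equal(combine_sinograms(list(sa, list(sb, 0)))$counts, sa$counts)
})

test_that("per-view mass is conserved without attenuation", {
  fx <- fixtures()
  s <- forward_project(fx$scene$activity, NULL, fx$orbit, fx$collimator,
                       "none")
  total_activity <- sum(fx$scene$activity$values) * fx$grid$voxel_mm^3
  per_view <- apply(s$counts, 3, sum)
  expect_true(all(abs(per_view - total_activity) / total_activity < 0.01))
})

test_that("the per-plane blur itself preserves mass to 1e-6", {
  # compare against the unblurred geometric projection of the same volume:
  # any difference in per-view totals is mass lost or created by the blur
  # (the shared rotation resampling cancels)
  g <- grid_spec(32, 32, 32, 4)
  p <- make_point_source(g, c(-2, -2, -2), 1)
  orbit <- orbit_spec("circular", radius_mm = 80, n_views = 8)
  blurred <- forward_project(p, NULL, orbit, collimator_model(3, 0.02), "none")
  geom <- forward_project_geometric(p, NULL, orbit, "none")
  tb <- apply(blurred$counts, 3, sum)
  tg <- apply(geom$counts, 3, sum)
  expect_true(all(abs(tb - tg) / tg < 1e-6))
})

test_that("isocentric point projects with FWHM(orbit radius) in every view", {
  g <- grid_spec(64, 64, 32, 4)
  p <- make_point_source(g, c(-2, -2, 0), 1)   # a voxel centre
  orbit <- orbit_spec("circular", radius_mm = 180, n_views = 12)
  coll <- collimator_model(3.0, 0.045)
  s <- forward_project(p, NULL, orbit, coll, "none")
  expected <- 3.0 + 0.045 * 180     # FWHM at the orbit radius, ~11.1 mm
  cross <- function(x1, x2, y1, y2, h) x1 + (h - y1) / (y2 - y1) * (x2 - x1)
  for (v in c(1, 4, 8)) {
    prof <- apply(s$counts[, , v], 1, sum)
    pk <- which.max(prof)
    half <- prof[pk] / 2
    xs <- (seq_along(prof) - pk) * g$voxel_mm
    i <- max(which(prof[1:pk] < half))
    j <- pk - 1 + min(which(prof[pk:length(prof)] < half))
    lo <- cross(xs[i], xs[i + 1], prof[i], prof[i + 1], half)
    hi <- cross(xs[j - 1], xs[j], prof[j - 1], prof[j], half)
    expect_equal(hi - lo, expected, tolerance = 2 / expected)  # half a bin
  }
})

test_that("attenuation never increases counts and matches the closed form for a central point", {
  g <- grid_spec(64, 64, 32, 4)
  rad <- 80
  cyl <- make_elliptical_cylinder(g, rad, rad, 120, 1)
  mu <- make_attenuation_map(cyl, 0.0154)
  orbit <- orbit_spec("circular", radius_mm = 180, n_views = 8)
  sharp <- collimator_model(0.5, 0)
  p <- make_point_source(g, c(-2, -2, -2), 1)
  s_att <- forward_project(p, mu, orbit, sharp, "full")
  s_free <- forward_project(p, NULL, orbit, sharp, "none")
  expect_true(all(s_att$counts <= s_free$counts + 1e-12))
  ratio <- apply(s_att$counts, 3, sum) / apply(s_free$counts, 3, sum)
  # closed-form line integral: exp(-mu x path from the point to the surface
  # along each view's ray), with the point half a voxel off-centre
  p0 <- c(-2, -2)
  ang <- view_angles(orbit)
  oracle <- vapply(seq_along(ang), function(v) {
    d <- c(cos(ang[v]), sin(ang[v]))
    tt <- uniroot(function(t) sum((p0 + t * d)^2) - rad^2, c(0, 2 * rad),
                  tol = 1e-10)$root
    exp(-0.0154 * tt)
  }, 0)
  expect_equal(ratio, oracle, tolerance = 0.02)
})

test_that("count scaling is exact and idempotent; zero input errors", {
  fx <- fixtures()
  s <- scale_to_total_counts(fx$sino, 5e6)
  expect_equal(sum(s$counts), 5e6, tolerance = 1e-9)
  s2 <- scale_to_total_counts(s, 5e6)
  expect_equal(s2$counts, s$counts, tolerance = 1e-12)
  zero <- sinogram(array(0, dim(s$counts)), s$orbit, s$detector)
  expect_error(scale_to_total_counts(zero, 1e6), "all-zero")
})

test_that("Poisson noise: zeros stay zero, seeds reproduce, means are unbiased", {
  fx <- fixtures()
  s <- scale_to_total_counts(fx$sino, 2e5)
  n1 <- add_poisson_noise(s, 11)
  n2 <- add_poisson_noise(s, 11)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(n1$counts[s$counts == 0] == 0))
  # 1e4 bins of mean 100: sample mean within 3 standard errors
  flat <- sinogram(array(100, c(25, 20, 20)),
                   orbit_spec(n_views = 20), detector_spec(25, 4, 20, 4))
  draw <- add_poisson_noise(flat, 99)
  se <- 10 / sqrt(length(flat$counts))
  expect_lt(abs(mean(draw$counts) - 100), 3 * se)
})

test_that("rebinning preserves counts and coarsens the detector", {
  fx <- fixtures()
  r <- rebin_sinogram(fx$sino, 2)
  expect_equal(sum(r$counts), sum(fx$sino$counts))
  expect_equal(dim(r$counts), c(16, 16, 20))
  expect_equal(r$detector$bin_mm, 8)
  expect_equal(r$counts[1, 1, 1], sum(fx$sino$counts[1:2, 1:2, 1]))
})

test_that("sinogram constructor enforces geometry consistency", {
  o <- orbit_spec(n_views = 10)
  d <- detector_spec(8, 4, 8, 4)
  expect_error(sinogram(array(1, c(8, 8, 9)), o, d), "shape")
  expect_error(sinogram(array(-1, c(8, 8, 10)), o, d), "non-negative")
  s1 <- sinogram(array(1, c(8, 8, 10)), o, d)
  s2 <- sinogram(array(1, c(8, 8, 10)), orbit_spec(radius_mm = 100, n_views = 10), d)
  expect_error(combine_sinograms(list(s1, s2)), "mismatch")
})
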