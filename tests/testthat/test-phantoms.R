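# independent voxel-centre inclusion oracle used throughout this file
oracle_count_ellcyl <- function(grid, a, b, len) {
  ax <- grid_axes(grid)
  n <- 0L
  for (k in seq_along(ax$z)) {
    if (abs(ax$z[k]) > len / 2) next
    for (j in seq_along(ax$y)) for (i in seq_along(ax$x)) {
      if ((ax$x[i] / a)^2 + (ax$y[j] / b)^2 <= 1) n <- n + 1L
    }
  }
  n
}

oracle_count_sphere <- function(grid, centre, r) {
  ax <- grid_axes(grid)
  n <- 0L
  for (k in seq_along(ax$z)) for (j in seq_along(ax$y)) for (i in seq_along(ax$x)) {
    if ((ax$x[i] - centre[1])^2 + (ax$y[j] - centre[2])^2 +
        (ax$z[k] - centre[3])^2 <= r^2) n <- n + 1L
  }
  n
}

test_that("elliptical cylinder matches the centre-inclusion oracle at full scale", {
  g <- grid_spec(128, 128, 64, 4)
  vol <- make_elliptical_cylinder(g, 152, 108, 216, 1)
  n <- sum(vol$values > 0)
  expect_identical(n, oracle_count_ellcyl(g, 152, 108, 216))
  # ~ pi * 38 * 27 * 54 voxels for the analytic solid
  expect_lt(abs(n - pi * 38 * 27 * 54) / (pi * 38 * 27 * 54), 0.02)
})

test_that("degenerate and indicator cylinder cases", {
  g <- grid_spec(32, 32, 32, 4)
  expect_equal(sum(make_elliptical_cylinder(g, 0, 40, 100, 1)$values), 0)
  v <- make_elliptical_cylinder(g, 50, 40, 100, 1)
  expect_equal(max(v$values), 1)
  expect_true(all(v$values %in% c(0, 1)))
  expect_error(make_elliptical_cylinder(g, 200, 40, 100), "x \\(major")
  expect_error(make_elliptical_cylinder(g, 50, 40, 500), "z \\(length")
})

test_that("lesions take TBR x background and must stay inside the support", {
  g <- grid_spec(64, 64, 32, 4)
  bg <- make_elliptical_cylinder(g, 100, 72, 120, 1)
  les <- lesion_spec(c(0, 0, 0), 36, 10)
  act <- add_lesion(bg, les, 1)
  m <- lesion_mask(g, les)
  expect_true(all(act$values[m] == 10))
  expect_identical(sum(m), oracle_count_sphere(g, c(0, 0, 0), 36))
  # TBR = 1 leaves the volume unchanged
  expect_equal(add_lesion(bg, lesion_spec(c(0, 0, 0), 36, 1), 1)$values,
               bg$values)
  # 8 mm sphere against the oracle
  les8 <- lesion_spec(c(20, 0, 0), 8, 5)
  expect_identical(sum(lesion_mask(g, les8)),
                   oracle_count_sphere(g, c(20, 0, 0), 8))
  expect_error(add_lesion(bg, lesion_spec(c(98, 0, 0), 10, 5), 1), "overlaps")
})

test_that("sphere voxelization stays within 15% of the analytic volume", {
  g <- grid_spec(64, 64, 64, 4)
  for (r in c(8, 12, 20, 28, 36)) {
    n <- sum(pertspect:::sphere_mask(g, c(2, -2, 2), r))
    analytic <- 4 / 3 * pi * r^3 / g$voxel_mm^3
    expect_lt(abs(n - analytic) / analytic, 0.15)
  }
})

test_that("shell lesions carry an outer intensity and a reduced core", {
  g <- grid_spec(64, 64, 32, 4)
  bg <- make_elliptical_cylinder(g, 100, 72, 120, 1)
  les <- lesion_spec(c(0, 0, 0), 22.2, 4, kind = "shell",
                     inner_radius_mm = 11, inner_tbr = 1)
  act <- add_lesion(bg, les, 1)
  core <- pertspect:::sphere_mask(g, c(0, 0, 0), 11)
  shell <- lesion_mask(g, les) & !core
  expect_true(all(act$values[shell] == 4))
  expect_true(all(act$values[core] == 1))
})

test_that("attenuation map mirrors the activity support with uniform mu", {
  g <- grid_spec(64, 64, 64, 4)
  bg <- make_elliptical_cylinder(g, 100, 72, 216, 1)
  mu <- make_attenuation_map(bg, 0.0154)
  expect_identical(mu$values > 0, bg$values > 0)
  # line integral across the minor diameter (216 mm length along z at x=y=0)
  iy <- world_to_index(g, c(0, 0, 0))[2]
  col <- mu$values[world_to_index(g, c(0, 0, 0))[1], , 24]
  expect_equal(sum(col) * g$voxel_mm, 0.0154 * 144, tolerance = 0.03)
  expect_error(make_attenuation_map(bg, 0), "mu_per_mm")
  empty <- volume_image(array(0, c(64, 64, 64)), g)
  expect_equal(sum(make_attenuation_map(empty, 0.0154)$values), 0)
})

test_that("point sources occupy exactly one voxel with the stated mass", {
  g <- grid_spec(96, 96, 48, 4)
  p <- make_point_source(g, c(0, 0, 0), 7)
  expect_equal(sum(p$values > 0), 1)
  expect_equal(sum(p$values), 7)
  # tie at the origin of an even grid breaks toward the lower index
  expect_equal(which(p$values > 0, arr.ind = TRUE)[1, ], c(48, 48, 24),
               ignore_attr = TRUE)
  expect_error(make_point_source(g, c(500, 0, 0)), "outside")
  # centre / edge voxel / 2 voxels outside a 36 mm lesion are expressible
  for (x in c(0, 34, 36 + 2 * 4)) {
    q <- make_point_source(g, c(x, 0, 0), 1)
    expect_equal(sum(q$values), 1)
  }
})

test_that("torso scenes encode the stated lesion intensity ratios", {
  g <- grid_spec(96, 96, 48, 4)
  bone <- make_torso_scene("bone", g, bladder_multiplier = 15)
  expect_true(all(bone$activity$values[bone$lesion_masks$femoral] == 5))
  expect_equal(max(bone$activity$values), 15)   # bladder at 15 x bone
  tek <- make_torso_scene("tektrotyd", g, lesions = "uniform6.25")
  spleen_val <- 6.25 / 1.2
  expect_true(any(abs(tek$activity$values - spleen_val) < 1e-12))
  expect_equal(max(tek$activity$values[tek$lesion_masks$uniform6.25]),
               1.2 * spleen_val)
  expect_error(make_torso_scene("pet", g), "arg")
  expect_error(make_torso_scene("bone", g, lesions = "liver"), "unknown bone")
  # regeneration is bit-identical
  bone2 <- make_torso_scene("bone", g, bladder_multiplier = 15)
  expect_identical(bone$activity$values, bone2$activity$values)
})

test_that("ring phantom zeroes the interior but keeps the wall", {
  g <- grid_spec(96, 96, 48, 4)
  ring <- make_ring_cylinder(g, length_mm = 180)
  inner <- pertspect:::ellcyl_mask(g, 152 - 30, 108 - 30, 180)
  expect_true(all(ring$values[inner] == 0))
  expect_gt(sum(ring$values), 0)
})
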