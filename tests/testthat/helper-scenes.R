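# Shared miniature study conditions: a scaled-down elliptical phantom on a
# 64 x 64 x 32 grid whose perturbation pipeline runs in seconds.  Results
# are cached per test run so several test files can share one computation.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

mini_grid <- function() grid_spec(64, 64, 32, 4)

mini_orbit <- function(n_views = 40) {
  orbit_spec("circular", radius_mm = 180, n_views = n_views)
}

mini_settings <- function(checkpoints = seq(20, 200, 20)) {
  recon_settings(10L, 20L, checkpoints = checkpoints)
}

mini_scene <- function(lesion = NULL) {
  simple_scene(mini_grid(), lesion, major_mm = 100, minor_mm = 72,
               length_mm = 120)
}

# central 24 mm radius TBR-10 lesion, noise-free, full perturbation pipeline
mini_case_central <- function() {
  cached("case_central", {
    les <- lesion_spec(c(0, 0, 0), 24, 10)
    scene <- mini_scene(les)
    sim <- simulate_scene_sinogram(scene, mini_orbit())
    case <- run_perturbation_case(sim$sino, scene$mu, mini_grid(), c(0, 0, 0),
                                  settings = mini_settings())
    list(scene = scene, sim = sim, case = case)
  })
}

# 16 mm radius TBR-10 lesion centred 48 mm off-axis (anisotropic PSF)
mini_case_offcentre <- function() {
  cached("case_offcentre", {
    les <- lesion_spec(c(48, 0, 0), 16, 10)
    scene <- mini_scene(les)
    sim <- simulate_scene_sinogram(scene, mini_orbit())
    case <- run_perturbation_case(sim$sino, scene$mu, mini_grid(), c(48, 0, 0),
                                  settings = mini_settings())
    list(scene = scene, sim = sim, case = case)
  })
}

# isocentre (non-specific) PSF of the same off-centre scene
mini_case_nonspecific <- function() {
  cached("case_nonspecific", {
    off <- mini_case_offcentre()
    run_perturbation_case(off$sim$sino, off$scene$mu, mini_grid(), c(0, 0, 0),
                          settings = mini_settings())
  })
}

fixtures <- function() cached("fixtures", make_fixtures(1L))
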