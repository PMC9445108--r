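# pertspect

Perturbation-based PSF estimation and Single Target Correction for
quantitative 99mTc SPECT — a self-contained simulation and correction
workbench.

## The problem

Activity concentrations of small objects are underestimated in SPECT
because of limited spatial resolution (the partial volume effect).
Partial volume correction (PVC) needs the reconstructed point spread
function (PSF), but in SPECT the PSF is *case-specific*: the
distance-dependent collimator response makes it vary across the field of
view, and OSEM reconstruction makes it depend on the surrounding activity
distribution and the number of updates. `pertspect` is for physicists and
methods researchers who want to study — entirely in simulation — whether
measuring the PSF per case by **perturbation** makes PVC quantitatively
accurate in oncology-like imaging scenarios.

## The method

1. **Simulate** projection data of a digital phantom with a rotation-based
   projector: distance-dependent Gaussian collimator blur
   (`FWHM(d) = fwhm0 + slope·d`), plane-by-plane attenuation, optional
   Poisson noise at clinical count levels.
2. **Reconstruct** with OSEM (10 subsets × 20 iterations = 200 updates),
   without resolution modelling and with a deliberately simplified
   attenuation correction.
3. **Perturb**: add the projections of a single-voxel point source, scaled
   so the reconstructed point contrast stays below 0.1; reconstruct
   perturbed and unperturbed data identically; subtract. The difference
   image is the local reconstructed PSF.
4. **Fit** 2D Gaussians in the three orthogonal planes through the point
   (offset fixed at zero, rotation fixed from the point azimuth); average
   each direction's two plane estimates into radial/tangential/axial FWHMs
   with covariance-based uncertainties.
5. **Correct** the lesion with Single Target Correction (STC): ten
   iterations of four voxelwise stages — target spill-in, target
   spill-out (`t = s_T / H m_T`), background spill-in, background
   spill-out — using the fitted anisotropic Gaussian kernel `H`, with a
   non-negativity constraint.
6. **Evaluate**: regional mean values (RMVs) against ground truth, and the
   local RMSE of the reconstruction against the ground truth convolved
   with the estimated PSF,
   `RMSE = sqrt(mean((R_i - C_i)^2))` over a local volume.

## A worked example

```r
library(pertspect)

grid  <- grid_spec(96, 96, 48, 4)                       # 4 mm voxels
orbit <- orbit_spec("circular", radius_mm = 260, n_views = 60)
scene <- simple_scene(grid, lesion_spec(c(0, 0, 0), 36, 10))  # TBR 10

sim  <- simulate_scene_sinogram(scene, orbit)
case <- run_perturbation_case(sim$sino, scene$mu, grid, c(0, 0, 0))
case$psf[["200"]]
#> <psf_estimate> FWHM r/t/ax = 14.64/14.75/14.69 mm (sd 0.037/0.038/0.021),
#>   theta 0.0 deg, update 200, contrast 0.0589, valid

pv <- pvc_over_series(case, scene$lesion_mask, scene$body_mask,
                      updates = c(50, 100, 200))
round(cbind(pv$update,
            percent_deviation(pv$rmv_uncorrected, scene$gt_rmv),
            percent_deviation(pv$rmv_corrected, scene$gt_rmv)), 2)
#>      [,1]   [,2] [,3]
#> [1,]   50 -18.50 0.29
#> [2,]  100 -18.41 0.02
#> [3,]  200 -18.41 -0.07
```

Reading: the uncorrected lesion RMV underestimates the ground truth by
~18% (the partial volume effect at this lesion size and resolution);
after STC with the perturbation-estimated PSF the corrected RMV is within
a fraction of a percent of truth once enough OSEM updates are used. The
fitted PSF at the isocentre is isotropic to well under 1%; at off-centre
positions the same pipeline yields the expected anisotropy
(radial > axial > tangential).

Scripted experiments reproduce the study sweeps
(`run_experiment("pvc_simple")`, `"fwhm_vs_updates"`, `"pvc_torso"`,
`"bladder_sensitivity"`, ...), each returning a provenance-tagged data
frame.

## Layout

- `R/`, `src/` — phantoms, acquisition geometry, projector and OSEM
  (RcppArmadillo), perturbation + fitting, STC, evaluation drivers, I/O
  (NIfTI, Interfile 3.3, YAML configs).
- `vignettes/perturbation-pvc.Rmd` — the methods vignette: model,
  assumptions, parameter choices, numerical details, limitations.
- `tests/testthat/` — unit, property and acceptance-level tests with
  in-code fixtures.
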