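test_that("rasterization paints compartment concentrations exactly", {
  spec <- small_torso()
  vol <- rasterize_phantom(spec, bkg_conc_kbq_ml = 2, sphere_conc_kbq_ml = 16,
                           supersampling = 4)
  # voxel at the body centre away from spheres -> background
  ctr <- round(-vol$origin / vol$spacing) + 1
  expect_equal(vol$voxels[ctr[1], ctr[2], ctr[3] + 10], 2000)
  # voxel at a sphere centre -> sphere concentration
  s <- spec$spheres[[1]]
  si <- round((s$center - vol$origin) / vol$spacing) + 1
  expect_equal(vol$voxels[si[1], si[2], si[3]], 16000)
  # exterior voxel -> 0
  expect_equal(vol$voxels[1, 1, 1], 0)
})

test_that("painted sphere activity matches the analytic sphere volume", {
  spec <- small_torso()
  bkg <- rasterize_phantom(spec, 2, 2, supersampling = 4)
  hot <- rasterize_phantom(spec, 2, 16, supersampling = 4)
  vox_ml <- prod(hot$spacing) / 1000
  for (s in spec$spheres) {
    R <- s$inner_diameter_mm / 2
    box <- 2 * (R + 4)
    ix <- which(abs(hot$origin[1] + (seq_len(dim(hot$voxels)[1]) - 1) *
                      hot$spacing[1] - s$center[1]) < box / 2)
    iy <- which(abs(hot$origin[2] + (seq_len(dim(hot$voxels)[2]) - 1) *
                      hot$spacing[2] - s$center[2]) < box / 2)
    iz <- which(abs(hot$origin[3] + (seq_len(dim(hot$voxels)[3]) - 1) *
                      hot$spacing[3] - s$center[3]) < box / 2)
    extra_bq <- sum(hot$voxels[ix, iy, iz] - bkg$voxels[ix, iy, iz]) * vox_ml
    truth_bq <- (16000 - 2000) * (pi / 6) * s$inner_diameter_mm^3 / 1000
    expect_equal(extra_bq, truth_bq, tolerance = 0.005)
  }
})

test_that("an undersized explicit grid is rejected", {
  expect_error(rasterize_phantom(small_torso(), 2, 16, shape = c(30, 30, 30)),
               "exceeds grid")
})

test_that("simulation is the identity when blur, noise and bias are off", {
  truth <- rasterize_phantom(small_torso(), 2, 16)
  out <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 0,
                                                noise_sigma0 = 0,
                                                calibration_bias = 1))
  expect_equal(out$voxels, truth$voxels)
})

test_that("simulation is deterministic given the seed and linear in bias", {
  truth <- rasterize_phantom(small_torso(), 2, 16)
  cfg <- simulation_config(psf_fwhm_mm = 4, noise_sigma0 = 100, seed = 99)
  a <- simulate_scan(truth, cfg)
  b <- simulate_scan(truth, cfg)
  expect_identical(a$voxels, b$voxels)
  c2 <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 4,
                                               noise_sigma0 = 100, seed = 100))
  expect_false(identical(a$voxels, c2$voxels))
  # noise-free: bias scales the blurred image exactly
  nf1 <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 4,
                                                calibration_bias = 1))
  nf2 <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 4,
                                                calibration_bias = 1.04))
  expect_equal(nf2$voxels, 1.04 * nf1$voxels, tolerance = 1e-12)
})

test_that("Gaussian blur conserves activity away from the grid edges", {
  truth <- rasterize_phantom(small_torso(), 2, 16, margin_mm = 20)
  blurred <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 5))
  expect_equal(sum(blurred$voxels) / sum(truth$voxels), 1, tolerance = 1e-3)
})

test_that("mean of noise realizations converges to the noise-free image", {
  spec <- phantom_spec("uniform_cylinder", axial_length_mm = 60,
                       cylinder_diameter_mm = 60, name = "mini")
  truth <- rasterize_phantom(spec, 5, spacing = c(4, 4, 4), margin_mm = 12,
                             supersampling = 2)
  nf <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 5,
                                               noise_sigma0 = 0))
  N <- 50
  sigma0 <- 250
  acc <- array(0, dim(nf$voxels))
  for (i in seq_len(N)) {
    acc <- acc + simulate_scan(truth, simulation_config(
      psf_fwhm_mm = 5, noise_sigma0 = sigma0, noise_reference = 5000,
      seed = 1000 + i))$voxels
  }
  avg <- acc / N
  # phantom-interior mean: sd of the mean over n voxels and N realizations
  interior <- nf$voxels > 4900
  n <- sum(interior)
  sd_mean <- sigma0 * sqrt(mean(nf$voxels[interior]) / 5000) / sqrt(n * N)
  expect_lt(abs(mean(avg[interior]) - mean(nf$voxels[interior])),
            3 * sd_mean)
})

test_that("closed-form sphere recovery matches the brute-force convolution", {
  # limits
  expect_equal(analytic_sphere_mean_rc(37, 0), 1)
  expect_lt(analytic_sphere_mean_rc(0.5, 8), 0.01)
  expect_gt(analytic_sphere_mean_rc(10, 5), analytic_sphere_mean_rc(10, 8))
  # frozen values from an independent 0.25-mm fine-grid convolution
  expect_equal(analytic_sphere_mean_rc(37, 5), 0.863277, tolerance = 2e-4)
  expect_equal(analytic_sphere_mean_rc(10, 5), 0.522438, tolerance = 5e-4)
  expect_equal(analytic_sphere_mean_rc(37, 1), 0.972571, tolerance = 2e-4)
  # live cross-check against the helper oracle at a non-tabulated setting
  expect_equal(analytic_sphere_mean_rc(17, 6.5),
               brute_sphere_mean_rc(17, 6.5, h = 0.5), tolerance = 3e-3)
})

test_that("fixtures carry their ground truth in the manifest", {
  fx <- make_fixture("calibration_quarterly")
  expect_equal(fx$manifest$bkg_conc_kbq_ml, 5)
  expect_equal(fx$manifest$injected_bias, 1)
  expect_identical(fx$manifest$phantom, "uniform20")

  fx2 <- make_fixture("rc_annual", overrides = list(calibration_bias = 1.06))
  expect_equal(fx2$manifest$injected_bias, 1.06)
  expect_equal(fx2$manifest$bkg_conc_kbq_ml, 2)
  expect_equal(fx2$manifest$contrast, 8)
  expect_equal(fx2$manifest$sphere_conc_kbq_ml, 16)

  expect_error(make_fixture("rc_annual", overrides = list(nonsense = 1)),
               "unknown overrides")
})
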