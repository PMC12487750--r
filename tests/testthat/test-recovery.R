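test_that("centroid localization recovers true sphere centers", {
  spec <- small_torso()
  truth <- rasterize_phantom(spec, 2, 16)
  blurred <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 5))
  s <- spec$spheres[[1]]
  # symmetric blurred sphere, seed at truth
  ctr <- locate_sphere_centroid(blurred, s$center, s$inner_diameter_mm,
                                background = 2000)
  expect_lt(sqrt(sum((ctr - s$center)^2)), 0.05)
  # seed offset by 3 mm still converges
  ctr2 <- locate_sphere_centroid(blurred, s$center + c(2, -2, 1),
                                 s$inner_diameter_mm, background = 2000)
  expect_lt(sqrt(sum((ctr2 - s$center)^2)), 0.2)
  # background-only region -> detection error
  expect_error(locate_sphere_centroid(blurred, c(0, -40, 20), 10,
                                      background = 2100),
               "no signal above background")
  expect_error(locate_sphere_centroid(blurred, c(999, 0, 0), 10),
               "outside the image grid")
})

test_that("sphere VOI statistics on a uniform image are the uniform value", {
  spec <- small_torso()
  truth <- rasterize_phantom(spec, 7, 7)  # spheres same as background
  st <- sphere_voi_stats(truth, c(0, 0, -15), 20)
  expect_equal(st$C_mean, 7000)
  expect_equal(st$C_max, 7000)
  expect_equal(st$C_peak, 7000)
  # the 1-mL peak VOI has the closed-form diameter
  expect_equal(peak_voi_diameter(1), (6000 / pi)^(1 / 3))
  expect_equal(peak_voi_diameter(1), 12.407, tolerance = 1e-4)
})

test_that("metric ordering holds on a noise-free blurred 37-mm sphere", {
  cv <- iq_curve()
  row <- cv[cv$diameter_mm == 37, ]
  expect_gte(row$C_max, row$C_peak)
  expect_gte(row$C_peak, row$C_mean)
})

test_that("tiny spheres below the voxel size ask for supersampling", {
  spec <- small_torso()
  truth <- rasterize_phantom(spec, 2, 16)
  off_lattice <- truth$origin[1:3] + truth$spacing / 2 + c(20, 10, 14)
  expect_error(sphere_voi_stats(truth, off_lattice, 0.9), "supersample")
})

test_that("CRC, RC and the conversion formulas agree with hand arithmetic", {
  expect_equal(crc(1.05, 1.05, 8, 1), 0)       # no contrast recovered
  expect_equal(crc(8, 1, 8, 1), 1)             # perfect recovery
  expect_equal(crc(7.2, 1.05, 8, 1), 0.83673469, tolerance = 1e-7)
  expect_error(crc(7.2, 0, 8, 1), "C_bkg")
  expect_error(crc(7.2, 1, 1, 1), "undefined")

  expect_equal(rc(4, 4), 1)
  expect_equal(rc(0, 4), 0)
  expect_error(rc(1, 0), "A_sphere")

  expect_equal(rc_to_crc(1, 8, 1), 1)
  expect_equal(rc_to_crc(0.9, 8, 1.05), 0.83673469, tolerance = 1e-7)
  # the two formulas are consistent: Eq-style cross-check
  expect_equal(rc_to_crc(0.9, 8, 1.05), crc(7.2, 1.05, 8, 1), tolerance = 1e-12)
  expect_error(rc_to_crc(0.9, 1, 1), "contrast")
})

test_that("rc_to_crc and crc_to_rc are exact algebraic inverses", {
  set.seed(7)
  for (i in 1:20) {
    r0 <- runif(1, 0.2, 1.2)
    ctr <- runif(1, 2, 20)
    b <- runif(1, 0.8, 1.2)
    expect_equal(crc_to_rc(rc_to_crc(r0, ctr, b), ctr, b), r0,
                 tolerance = 1e-12)
  }
})

test_that("recovery analysis measures the expected curve on the IQ phantom", {
  cv <- iq_curve()
  expect_s3_class(cv, "recovery_curve")
  expect_equal(cv$diameter_mm, c(10, 13, 17, 22, 28, 37))
  expect_equal(attr(cv, "contrast"), 8, tolerance = 1e-9)
  expect_equal(attr(cv, "calibration_bias"), 1, tolerance = 0.005)
  expect_length(attr(cv, "failures"), 0)
  # noise-free mean CRC tracks the analytic partial-volume prediction
  # (voxel-aperture corrected) within 2%
  for (i in seq_len(nrow(cv))) {
    pred <- analytic_sphere_mean_rc(cv$diameter_mm[i], effective_psf_fwhm(5, 2))
    expect_equal(cv$CRC_mean[i], pred, tolerance = 0.02)
  }
  # monotone in diameter, and max >= peak >= mean throughout for d >= 17
  expect_true(all(diff(cv$CRC_mean) > 0))
  big <- cv$diameter_mm >= 17
  expect_true(all(cv$C_max[big] >= cv$C_peak[big] &
                  cv$C_peak[big] >= cv$C_mean[big]))
})

test_that("fwhm-0, bias-1 noise-free recovery is exact for lattice-aligned spheres", {
  # sphere centers on voxel centers so the painted max equals the fill value
  spec <- phantom_spec("torso_iq", axial_length_mm = 80,
                       body_semiaxes_mm = c(70, 60),
                       spheres = list(sphere_insert(22, c(28, 0, 0)),
                                      sphere_insert(14, c(-28, 0, 0))),
                       name = "aligned")
  truth <- rasterize_phantom(spec, 2, 16)
  cv <- analyze_recovery(truth, simple_fill(2, 1000, truth$acquisition_start),
                         simple_fill(16, 500, truth$acquisition_start,
                                     "sphere_stock"),
                         spec, bkg_rois = small_torso_rois())
  expect_equal(cv$CRC_max, c(1, 1), tolerance = 1e-9)
  expect_equal(cv$RC_max, c(1, 1), tolerance = 1e-9)
})

test_that("detection failures yield partial curves with flags", {
  # second sphere is declared outside the reconstructed volume (e.g. phantom
  # mispositioned): its detection fails, the rest of the curve survives
  spec <- phantom_spec("torso_iq", axial_length_mm = 80,
                       body_semiaxes_mm = c(70, 60),
                       spheres = list(sphere_insert(22, c(28, 0, 0)),
                                      sphere_insert(10, c(300, 0, 0))),
                       name = "mispositioned")
  truth <- rasterize_phantom(spec, 2, 16)
  blurred <- simulate_scan(truth, simulation_config(psf_fwhm_mm = 5))
  cv <- analyze_recovery(
    blurred, simple_fill(2, 1000, blurred$acquisition_start),
    simple_fill(16, 500, blurred$acquisition_start, "sphere_stock"),
    spec, bkg_rois = small_torso_rois())
  expect_length(attr(cv, "failures"), 1)
  expect_match(attr(cv, "failures"), "^300 mm|^10 mm")
  expect_equal(cv$diameter_mm, 22)
})

test_that("recovery curves serialize to CSV with their metadata", {
  cv <- iq_curve()
  path <- withr::local_tempfile(fileext = ".csv")
  write_recovery_csv(cv, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# contrast=8")
  back <- read.csv(path, comment.char = "#")
  expect_equal(back$CRC_max, cv$CRC_max, tolerance = 1e-9)
})
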