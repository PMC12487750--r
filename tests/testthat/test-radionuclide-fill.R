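test_that("decay correction reproduces half-life arithmetic exactly", {
  t0 <- as.POSIXct("2026-03-01 08:00:00", tz = "UTC")
  expect_equal(decay_correct(100, t0, t0 + 12.7 * 3600, "Cu-64"), 50)
  expect_equal(decay_correct(100, t0, t0, "Cu-64"), 100)
  expect_equal(decay_correct(100, t0, t0 + 25.4 * 3600, "Cu-64"), 25)
  # backwards correction inverts decay
  expect_equal(decay_correct(50, t0 + 12.7 * 3600, t0, "Cu-64"), 100)
})

test_that("registry carries the long-lived nuclides with printed half-lives", {
  reg <- radionuclide_registry()
  expect_true(all(c("F-18", "Ga-68", "Cu-64", "Zr-89", "I-124") %in% reg$name))
  expect_equal(radionuclide("Cu-64")$half_life_min, 12.7 * 60)
  expect_equal(radionuclide("Zr-89")$half_life_min, 3.25 * 1440)
  expect_equal(radionuclide("I-124")$half_life_min, 4.2 * 1440)
  expect_identical(radionuclide("18F")$name, "F-18")
  expect_error(radionuclide("Tc-99m"), "Unknown radionuclide")
  expect_error(radionuclide("X", half_life_min = -1), "positive")
})

test_that("decay correction round-trips and is transitive", {
  t0 <- as.POSIXct("2026-03-01 08:00:00", tz = "UTC")
  for (nuc in c("F-18", "Ga-68", "Zr-89")) {
    for (dt_h in c(0.3, 5, 100)) {
      t1 <- t0 + dt_h * 3600
      a <- decay_correct(123.4, t0, t1, nuc)
      expect_equal(decay_correct(a, t1, t0, nuc), 123.4, tolerance = 1e-12)
    }
  }
})

test_that("net activity is the difference of independently corrected assays", {
  t0 <- as.POSIXct("2026-03-01 08:00:00", tz = "UTC")
  f <- fill_record("Cu-64", activity_assay(200, t0), activity_assay(10, t0),
                   t0, 9000)
  expect_equal(net_activity_at(f, t0), 190)
  expect_equal(net_activity_at(f, t0 + 12.7 * 3600), 95)
  expect_error(
    fill_record("Cu-64", activity_assay(10, t0), activity_assay(200, t0),
                t0, 9000),
    "residual exceeds")
})

test_that("net activity is invariant to the intermediate reference time", {
  t0 <- as.POSIXct("2026-03-01 08:00:00", tz = "UTC")
  # assays at different times; correct through arbitrary intermediates
  f <- fill_record("F-18", activity_assay(180, t0 - 600),
                   activity_assay(12, t0 + 300), t0, 6000)
  target <- t0 + 2 * 3600
  direct <- net_activity_at(f, target)
  for (mid_h in c(-3, 0.01, 1, 7)) {
    t_mid <- t0 + mid_h * 3600
    via <- decay_correct(net_activity_at(f, t_mid), t_mid, target, "F-18")
    expect_equal(via, direct, tolerance = 1e-10)
  }
})

test_that("volume from weight and concentration follow the fill arithmetic", {
  expect_equal(volume_from_weight(2000, 1000, 1.0), 1000)
  expect_equal(volume_from_weight(11197, 1999), 9214.58625526, tolerance = 1e-8)
  expect_error(volume_from_weight(1000, 1000), "nonpositive")

  t0 <- as.POSIXct("2026-03-01 08:00:00", tz = "UTC")
  f <- fill_record("F-18", activity_assay(38, t0), activity_assay(1, t0),
                   t0, 9250)
  expect_equal(concentration_at(f, t0), 4.0)  # 37 MBq in 9250 mL
  z <- fill_record("F-18", activity_assay(5, t0), activity_assay(5, t0),
                   t0, 9250)
  expect_equal(concentration_at(z, t0), 0)
  # linear in net activity, inverse in volume
  f2 <- fill_record("F-18", activity_assay(75, t0), activity_assay(1, t0),
                    t0, 9250)
  expect_equal(concentration_at(f2, t0), 2 * concentration_at(f, t0))
  f3 <- fill_record("F-18", activity_assay(38, t0), activity_assay(1, t0),
                    t0, 2 * 9250)
  expect_equal(concentration_at(f3, t0), concentration_at(f, t0) / 2)
})

test_that("fill planner hits the recommended 8:1 concentrations", {
  plan <- plan_rc_fill(2)
  expect_equal(plan$sphere_conc_kbq_ml, 16)
  expect_equal(plan$contrast, 8)
  expect_equal(achieved_contrast(16, 2), 8)
  expect_equal(achieved_contrast(2, 2), 1)
  expect_equal(achieved_contrast(0, 2), 0)
  expect_error(achieved_contrast(16, 0), "> 0")
})

test_that("fill QC flags the recommended limits and nothing else", {
  expect_length(fill_qc("rc", bkg_conc_kbq_ml = 2, contrast = 8,
                        total_fov_activity_mbq = 20), 0)
  expect_match(fill_qc("rc", bkg_conc_kbq_ml = 6.5), "exceeds limit")
  expect_match(fill_qc("calibration", bkg_conc_kbq_ml = 5,
                       total_fov_activity_mbq = 45), "dead-time")
  expect_match(fill_qc("calibration", bkg_conc_kbq_ml = 2), "below")
  expect_match(fill_qc("rc", bkg_conc_kbq_ml = 3, contrast = 4), "contrast")
  expect_match(fill_qc("rc", bkg_conc_kbq_ml = 3, clock_offsets_min = 1.5),
               "clock offset")
  # QC never raises
  expect_silent(fill_qc("rc", bkg_conc_kbq_ml = -1))
})

test_that("fill records survive a JSON round-trip", {
  t0 <- as.POSIXct("2026-03-01 08:00:00", tz = "UTC")
  fills <- list(
    background = fill_record("F-18", activity_assay(38, t0 - 300, "cal-A"),
                             activity_assay(1.5, t0 + 60, "cal-A"), t0, 9250),
    sphere_stock = fill_record("F-18", activity_assay(17, t0),
                               activity_assay(0.9, t0), t0, 1000,
                               "sphere_stock"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fill_json(fills, path)
  back <- read_fill_json(path)
  expect_named(back, c("background", "sphere_stock"))
  expect_equal(net_activity_at(back$background, t0),
               net_activity_at(fills$background, t0), tolerance = 1e-9)
  expect_equal(back$sphere_stock$compartment_kind, "sphere_stock")
  expect_equal(back$background$compartment_volume_ml, 9250)
})
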