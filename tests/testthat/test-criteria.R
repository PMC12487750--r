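# Synthetic calibration result (the criteria engine is a pure function of
# the summary numbers).
fake_cal_result <- function(bias, date = "2025-01-15") {
  structure(list(global_bias = bias,
                 acquisition_start = as.POSIXct(paste(date, "09:00:00"),
                                                tz = "UTC"),
                 A_bkg_kbq_ml = 5, axial_uniformity = 0,
                 radionuclide = "F-18"),
            class = "calibration_result")
}

# Synthetic recovery curve at given per-diameter CRC_max values.
fake_curve <- function(crc_max, diameters = c(10, 13, 17, 22, 28, 37)) {
  structure(data.frame(diameter_mm = diameters, CRC_max = crc_max),
            class = c("recovery_curve", "data.frame"),
            contrast = 8, calibration_bias = 1,
            acquisition_start = as.POSIXct("2025-01-15 09:00:00", tz = "UTC"),
            radionuclide = "F-18")
}

midpoints <- function(criteria = default_criteria()) {
  (criteria$crc_limits$min + criteria$crc_limits$max) / 2
}

test_that("tiered calibration tolerances follow the nuclide class", {
  expect_equal(calibration_tolerance("F-18", 1), 0.05)
  expect_equal(calibration_tolerance("Ga-68", 1), 0.05)
  expect_equal(calibration_tolerance("Zr-89", 1), 0.10)
  expect_equal(calibration_tolerance("F-18", 2), 0.10)
  expect_equal(calibration_tolerance("I-124", 2), 0.10)
})

test_that("calibration evaluation is inclusive at the printed boundary", {
  expect_true(evaluate_calibration(fake_cal_result(1.05), "F-18", 1)$passed)
  expect_true(evaluate_calibration(fake_cal_result(0.95), "F-18", 1)$passed)
  expect_false(evaluate_calibration(fake_cal_result(1.06), "F-18", 1)$passed)
  expect_false(evaluate_calibration(fake_cal_result(0.94), "F-18", 1)$passed)
  expect_true(evaluate_calibration(fake_cal_result(1.08), "Zr-89", 1)$passed)
  expect_false(evaluate_calibration(fake_cal_result(1.11), "Zr-89", 1)$passed)
  expect_true(evaluate_calibration(fake_cal_result(1.08), "F-18", 2)$passed)
  expect_error(evaluate_calibration(fake_cal_result(1.0), "Tc-99m", 1),
               "Unknown radionuclide")
})

test_that("CRC evaluation judges each sphere against its limits", {
  crit <- default_criteria()
  expect_true(evaluate_crc(fake_curve(midpoints()), crit)$passed)

  low10 <- midpoints(); low10[1] <- 0.44
  d <- evaluate_crc(fake_curve(low10), crit)
  expect_false(d$passed)
  expect_equal(d$findings$verdict[d$findings$item == "CRC_max_10mm"], "fail")

  high37 <- midpoints(); high37[6] <- 1.34
  d2 <- evaluate_crc(fake_curve(high37), crit)
  expect_false(d2$passed)
  expect_equal(d2$findings$verdict[d2$findings$item == "CRC_max_37mm"], "fail")

  # 7-mm characterization sphere is informational, never judged
  cv7 <- fake_curve(c(0.2, midpoints()), diameters = c(7, 10, 13, 17, 22, 28, 37))
  d3 <- evaluate_crc(cv7, crit)
  expect_true(d3$passed)
  expect_equal(d3$findings$verdict[d3$findings$item == "CRC_max_7mm"],
               "informational")

  # missing mandated diameter is an error
  expect_error(evaluate_crc(fake_curve(midpoints()[-1],
                                       diameters = c(13, 17, 22, 28, 37)),
                            crit),
               "missing mandated")
})

test_that("validity windows follow the quarterly/annual calendar", {
  w <- validity_window(as.Date("2025-01-15"), "F-18", "calibration")
  expect_equal(w$valid_from, as.Date("2025-01-15"))
  expect_equal(w$valid_until, as.Date("2025-04-15"))
  expect_equal(validity_window(as.Date("2025-01-15"), "Ga-68",
                               "calibration")$valid_until,
               as.Date("2025-04-15"))
  expect_equal(validity_window(as.Date("2025-01-15"), "Zr-89",
                               "calibration")$valid_until,
               as.Date("2026-01-15"))
  expect_equal(validity_window(as.Date("2025-01-15"), "F-18",
                               "recovery")$valid_until,
               as.Date("2026-01-15"))
})

test_that("revalidation triggers truncate the validity window", {
  d <- evaluate_calibration(fake_cal_result(1.0), "F-18", 1)
  ev <- data.frame(date = c("2025-02-01", "2025-03-01"),
                   kind = c("software_update", "major_service"))
  expect_equal(apply_events(d, ev)$valid_until, as.Date("2025-02-01"))
  before <- data.frame(date = "2024-12-01", kind = "software_update")
  expect_equal(apply_events(d, before)$valid_until, d$valid_until)
  other <- data.frame(date = "2025-02-01", kind = "room_repainted")
  expect_equal(apply_events(d, other)$valid_until, d$valid_until)
})

test_that("decisions are pure and serialize deterministically", {
  d1 <- evaluate_calibration(fake_cal_result(1.032), "F-18", 1)
  d2 <- evaluate_calibration(fake_cal_result(1.032), "F-18", 1)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_decision_json(d1, p1)
  write_decision_json(d2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # sign-off is represented, pending by default
  expect_false(d1$visual_review$signed_off)
})

test_that("tightening a tolerance never converts a fail into a pass", {
  crit <- default_criteria()
  biases <- seq(0.90, 1.10, by = 0.005)
  tols <- c(0.10, 0.08, 0.05, 0.03, 0.01)
  prev_pass <- rep(TRUE, length(biases))
  for (tol in tols) {
    crit$calibration$tier1[["F-18"]] <- tol
    pass <- vapply(biases, function(b) {
      evaluate_calibration(fake_cal_result(b), "F-18", 1, crit)$passed
    }, TRUE)
    expect_true(all(prev_pass | !pass))  # pass set only shrinks
    prev_pass <- pass
  }
})

test_that("criteria tables are data and load from custom JSON", {
  crit <- default_criteria()
  expect_equal(crit$contrast, 8)
  expect_identical(crit$metric, "max")
  expect_equal(sort(crit$crc_limits$diameter_mm), c(10, 13, 17, 22, 28, 37))
  expect_true(all(crit$crc_limits$min < crit$crc_limits$max))

  # a trial-specific table with an extra small sphere needs no code change
  custom <- crit
  custom$crc_limits <- rbind(data.frame(diameter_mm = 8, min = 0.2, max = 0.7),
                             crit$crc_limits)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(custom), path, auto_unbox = TRUE, digits = NA)
  crit2 <- read_criteria_json(path)
  cv <- fake_curve(c(0.5, midpoints()), diameters = c(8, 10, 13, 17, 22, 28, 37))
  expect_true(evaluate_crc(cv, crit2)$passed)
  cv$CRC_max[1] <- 0.1
  expect_false(evaluate_crc(cv, crit2)$passed)
})
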