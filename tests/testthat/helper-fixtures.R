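# Shared fixtures, computed once per test run on first use and memoised.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Noise-free image-quality fixture at the recommended fill (2 kBq/mL, 8:1)
# and its measured recovery curve.
iq_fixture <- function() cached("iq", make_fixture("rc_annual"))
iq_curve <- function() cached("iq_curve", {
  fx <- iq_fixture()
  analyze_recovery(fx$scan, fx$fills$background, fx$fills$sphere_stock,
                   fx$spec)
})

# Small two-sphere torso phantom for fast unit tests.
small_torso <- function() {
  phantom_spec("torso_iq", axial_length_mm = 80, body_semiaxes_mm = c(70, 60),
               spheres = list(sphere_insert(22, c(28, 0, 0)),
                              sphere_insert(10, c(-28, 0, 0))),
               cold_inserts = list(), name = "small_torso")
}

small_torso_rois <- function(z = 0) {
  ang <- seq(30, 330, by = 60) * pi / 180
  data.frame(x_mm = 48 * cos(ang), y_mm = 42 * sin(ang), z_mm = z,
             diameter_mm = 16)
}

# Fill records with assays at scan time (no decay book-keeping needed).
simple_fill <- function(conc_kbq_ml, volume_ml, time, kind = "background",
                        nuclide = "F-18") {
  fill_record(nuclide,
              activity_assay(conc_kbq_ml * volume_ml / 1000 + 1, time),
              activity_assay(1, time),
              time, volume_ml, kind)
}

t_scan <- as.POSIXct("2026-01-01 10:00:00", tz = "UTC")
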