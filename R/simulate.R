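# Synthetic phantom-scan simulator. The partial-volume model is a post-hoc
# isotropic Gaussian convolution of the painted ground truth (the metrics the
# package computes are defined on reconstructed images, for which a Gaussian
# PSF is the standard desk-scale surrogate); noise is Gaussian with variance
# proportional to the local mean, which keeps the ground truth analytic.

#' Create a simulation configuration
#'
#' @param psf_fwhm_mm Isotropic Gaussian PSF full width at half maximum, mm
#'   (>= 0; 0 disables blurring).
#' @param noise_sigma0 Noise standard deviation in Bq/mL at the reference
#'   concentration (>= 0; 0 disables noise).
#' @param noise_reference Reference concentration in Bq/mL at which the noise
#'   sd equals `noise_sigma0`; per-voxel sd scales with the square root of
#'   the local mean, `sigma0 * sqrt(max(v, 0) / reference)`.
#' @param calibration_bias Multiplicative calibration bias factor (> 0);
#'   1 means a perfectly calibrated scanner.
#' @param seed Integer seed; one generator per [simulate_scan()] call, so the
#'   same configuration reproduces bit-identical volumes.
#' @param supersampling Subvoxel sampling factor per axis used when painting
#'   ground truth (>= 1).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(psf_fwhm_mm = 5, noise_sigma0 = 0,
                              noise_reference = 5000, calibration_bias = 1,
                              seed = 1L, supersampling = 4L) {
  stopifnot(psf_fwhm_mm >= 0, noise_sigma0 >= 0, noise_reference > 0,
            calibration_bias > 0, supersampling >= 1)
  structure(list(psf_fwhm_mm = psf_fwhm_mm, noise_sigma0 = noise_sigma0,
                 noise_reference = noise_reference,
                 calibration_bias = calibration_bias, seed = as.integer(seed),
                 supersampling = as.integer(supersampling)),
            class = "simulation_config")
}

# Fractional area of each grid cell (centers cx x cy) inside the body
# cross-section, by ss x ss subcell sampling. `inside_fun(x, y)` is vectorized.
.xy_fraction <- function(cx, cy, h, ss, inside_fun) {
  off <- (seq_len(ss) - 0.5) / ss - 0.5  # subcell offsets in voxel units
  frac <- matrix(0, length(cx), length(cy))
  for (ox in off) {
    for (oy in off) {
      xs <- cx + ox * h[1]
      ys <- cy + oy * h[2]
      frac <- frac + outer(xs, ys, inside_fun)
    }
  }
  frac / ss^2
}

# Exact fractional overlap of voxel z-extents with [z0, z1]
.z_fraction <- function(cz, h, z0, z1) {
  lo <- pmax(cz - h / 2, z0)
  hi <- pmin(cz + h / 2, z1)
  pmax(hi - lo, 0) / h
}

#' Paint a filled phantom onto a voxel grid
#'
#' Produces the ground-truth volume: each voxel value is the volume-fraction
#' weighted mixture of the compartment concentrations (background, sphere
#' interior, cold insert = 0, exterior = 0), estimated by subvoxel sampling.
#'
#' @param spec A [phantom_spec()].
#' @param bkg_conc_kbq_ml Background concentration at scan time, kBq/mL.
#' @param sphere_conc_kbq_ml Sphere concentration at scan time, kBq/mL
#'   (ignored for phantoms without spheres).
#' @param spacing Voxel spacing, mm (scalar or 3-vector; default 2 mm
#'   isotropic, within the recommended 1.5--2.75 mm reconstruction range).
#' @param shape Optional grid shape (3 integers); defaults to the smallest
#'   grid covering the phantom plus `margin_mm` on every side. If a given
#'   grid does not cover the phantom an error is raised.
#' @param margin_mm Empty margin around the phantom for the default grid.
#' @param supersampling Subvoxel sampling factor per axis (>= 1).
#' @param acquisition_start Timestamp stamped on the volume.
#' @param nuclide Radionuclide name stamped on the volume.
#' @return An [image_volume()] in Bq/mL (truth; no blur, no noise).
#' @export
rasterize_phantom <- function(spec, bkg_conc_kbq_ml, sphere_conc_kbq_ml = 0,
                              spacing = c(2, 2, 2), shape = NULL,
                              margin_mm = 20, supersampling = 4L,
                              acquisition_start = as.POSIXct("2026-01-01 10:00:00", tz = "UTC"),
                              nuclide = "F-18") {
  stopifnot(inherits(spec, "phantom_spec"), supersampling >= 1)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  half_xy <- if (spec$kind == "uniform_cylinder") {
    rep(spec$cylinder_diameter_mm / 2, 2)
  } else spec$body_semiaxes_mm
  half <- c(half_xy, spec$axial_length_mm / 2)
  if (is.null(shape)) {
    shape <- ceiling(2 * (half + margin_mm) / spacing)
  } else {
    shape <- as.integer(shape)
    if (any((shape * spacing) / 2 < half)) {
      stop("phantom exceeds grid: increase shape or spacing", call. = FALSE)
    }
  }
  # grid centered on the phantom centroid (world origin)
  origin <- -(shape - 1) / 2 * spacing
  cx <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]

  body_in <- if (spec$kind == "uniform_cylinder") {
    r2 <- (spec$cylinder_diameter_mm / 2)^2
    function(x, y) (x^2 + y^2) < r2
  } else {
    a <- spec$body_semiaxes_mm[1]; b <- spec$body_semiaxes_mm[2]
    function(x, y) ((x / a)^2 + (y / b)^2) < 1
  }
  f_body_xy <- .xy_fraction(cx, cy, spacing, supersampling, body_in)
  f_z <- .z_fraction(cz, spacing[3], -half[3], half[3])

  bkg <- 1000 * bkg_conc_kbq_ml   # Bq/mL
  sph <- 1000 * sphere_conc_kbq_ml
  vox <- array(0, shape)
  for (iz in seq_len(shape[3])) vox[, , iz] <- f_body_xy * f_z[iz]
  # cold inserts: zero activity, subtract their (background) fraction
  for (ci in spec$cold_inserts) {
    if (!identical(ci$shape, "cylinder")) {
      stop("unsupported cold insert shape: ", ci$shape, call. = FALSE)
    }
    ctr <- unlist(ci$center)
    r2 <- (ci$diameter_mm / 2)^2
    f_xy <- .xy_fraction(cx, cy, spacing, supersampling,
                         function(x, y) ((x - ctr[1])^2 + (y - ctr[2])^2) < r2)
    len <- ci$length_mm %||% spec$axial_length_mm
    fz <- .z_fraction(cz, spacing[3], ctr[3] - len / 2, ctr[3] + len / 2)
    for (iz in seq_len(shape[3])) {
      vox[, , iz] <- vox[, , iz] - pmin(f_xy * fz[iz], vox[, , iz])
    }
  }
  vox <- vox * bkg

  # spheres: replace background with sphere concentration inside. Each
  # subcell contributes an antialiased coverage (planar surface
  # approximation within the subcell) rather than a binary in/out test,
  # which keeps the painted sphere volume accurate to well under 0.5%.
  off <- (seq_len(supersampling) - 0.5) / supersampling - 0.5
  sub <- as.matrix(expand.grid(off * spacing[1], off * spacing[2],
                               off * spacing[3]))
  h_sub <- prod(spacing / supersampling)^(1 / 3)
  for (s in spec$spheres) {
    R <- s$inner_diameter_mm / 2
    ix <- which(abs(cx - s$center[1]) <= R + spacing[1])
    iy <- which(abs(cy - s$center[2]) <= R + spacing[2])
    iz <- which(abs(cz - s$center[3]) <= R + spacing[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    ctr <- as.matrix(expand.grid(cx[ix], cy[iy], cz[iz]))
    frac <- numeric(nrow(ctr))
    for (k in seq_len(nrow(sub))) {
      dx <- ctr[, 1] + sub[k, 1] - s$center[1]
      dy <- ctr[, 2] + sub[k, 2] - s$center[2]
      dz <- ctr[, 3] + sub[k, 3] - s$center[3]
      r <- sqrt(dx * dx + dy * dy + dz * dz)
      frac <- frac + pmin(pmax((R - r) / h_sub + 0.5, 0), 1)
    }
    frac <- frac / nrow(sub)
    fr <- array(frac, c(length(ix), length(iy), length(iz)))
    vox[ix, iy, iz] <- vox[ix, iy, iz] + (sph - bkg) * fr
  }

  image_volume(vox, spacing, origin, acquisition_start, nuclide,
               meta = list(phantom = spec$name,
                           bkg_conc_kbq_ml = bkg_conc_kbq_ml,
                           sphere_conc_kbq_ml = sphere_conc_kbq_ml,
                           supersampling = supersampling))
}

# Separable Gaussian blur with zero padding (activity-conserving away from
# the grid edges). sigma_vox per axis in voxel units.
.gauss_blur3d <- function(A, sigma_vox) {
  d <- dim(A)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    kr <- max(1L, ceiling(4 * s))
    k <- dnorm(seq(-kr, kr), sd = s)
    k <- k / sum(k)
    n <- d[ax]
    out <- array(0, d)
    for (j in seq_along(k)) {
      sh <- j - kr - 1L
      dst <- max(1L, 1L - sh):min(n, n - sh)
      src <- dst + sh
      if (ax == 1) out[dst, , ] <- out[dst, , ] + k[j] * A[src, , ]
      else if (ax == 2) out[, dst, ] <- out[, dst, ] + k[j] * A[, src, ]
      else out[, , dst] <- out[, , dst] + k[j] * A[, , src]
    }
    A <- out
  }
  A
}

#' Simulate a PET acquisition of a ground-truth volume
#'
#' Applies, in order: isotropic Gaussian blur with `sigma = fwhm / 2.3548`
#' (the partial-volume model), multiplication by the calibration bias factor,
#' and heteroscedastic Gaussian noise with per-voxel
#' `sd = noise_sigma0 * sqrt(max(v, 0) / noise_reference)`. Nothing is
#' clipped: negative noise excursions are retained, as in reconstructed PET.
#' The RNG state is seeded from `config$seed` for the duration of the call
#' and restored afterwards, so identical inputs give bit-identical volumes.
#'
#' @param truth An [image_volume()] ground-truth volume.
#' @param config A [simulation_config()].
#' @return An [image_volume()] with simulation metadata in `$meta`.
#' @export
simulate_scan <- function(truth, config = simulation_config()) {
  stopifnot(inherits(truth, "image_volume"),
            inherits(config, "simulation_config"))
  A <- truth$voxels
  if (config$psf_fwhm_mm > 0) {
    sigma_vox <- (config$psf_fwhm_mm / 2.3548) / truth$spacing
    A <- .gauss_blur3d(A, sigma_vox)
  }
  A <- A * config$calibration_bias
  if (config$noise_sigma0 > 0) {
    sd <- config$noise_sigma0 * sqrt(pmax(A, 0) / config$noise_reference)
    noise <- withr::with_seed(config$seed, rnorm(length(A), sd = as.vector(sd)))
    A <- A + array(noise, dim(A))
  }
  image_volume(A, truth$spacing, truth$origin, truth$acquisition_start,
               truth$radionuclide,
               meta = c(truth$meta,
                        list(psf_fwhm_mm = config$psf_fwhm_mm,
                             injected_bias = config$calibration_bias,
                             noise_sigma0 = config$noise_sigma0,
                             noise_reference = config$noise_reference,
                             seed = config$seed)))
}

# Build a fill record whose concentration at `scan_time` equals the target,
# with assays performed `lead_min` minutes before the scan.
.fill_for_concentration <- function(conc_kbq_ml, volume_ml, nuclide, scan_time,
                                    kind, lead_min = 60, residual_mbq = 2) {
  nuc <- .as_nuclide(nuclide)
  t_fill <- .as_time(scan_time) - lead_min * 60
  net_scan_mbq <- conc_kbq_ml * volume_ml / 1000
  net_fill_mbq <- net_scan_mbq / 2^(-lead_min / nuc$half_life_min)
  fill_record(nuc,
              activity_assay(net_fill_mbq + residual_mbq, t_fill, "calibrator-1"),
              activity_assay(residual_mbq, t_fill, "calibrator-1"),
              t_fill, volume_ml, kind)
}

#' Generate a complete synthetic validation fixture
#'
#' * `calibration_quarterly`: the `uniform20` phantom filled at 5 kBq/mL
#'   (mid-range of the recommended 3--7 kBq/mL) with F-18, calibration bias
#'   1.0, PSF FWHM 5 mm.
#' * `rc_annual`: the `iq_nema` phantom at 2 kBq/mL background and 8:1
#'   sphere-to-background contrast (16 kBq/mL spheres) with F-18.
#'
#' Returns (and optionally writes) the ground-truth volume, the simulated
#' volume, the fill records, and a manifest recording all injected ground
#' truth, including the calibration bias.
#'
#' @param name `"calibration_quarterly"` or `"rc_annual"`.
#' @param overrides Named list overriding defaults: any of `bkg_conc_kbq_ml`,
#'   `contrast`, `psf_fwhm_mm`, `calibration_bias`, `noise_sigma0`,
#'   `noise_reference`, `seed`, `spacing`, `supersampling`, `nuclide`,
#'   `phantom` (a [phantom_spec()]), `acquisition_start`.
#' @param dir Optional output directory; when given, writes
#'   `truth.nii.gz`, `scan.nii.gz` (+ JSON sidecars), `fills.json` and
#'   `manifest.json`.
#' @return List with `truth`, `scan`, `fills`, `spec`, `manifest`.
#' @export
make_fixture <- function(name = c("calibration_quarterly", "rc_annual"),
                         overrides = list(), dir = NULL) {
  name <- match.arg(name)
  defaults <- if (name == "calibration_quarterly") {
    list(phantom = builtin_phantom("uniform20"), bkg_conc_kbq_ml = 5,
         contrast = NA, psf_fwhm_mm = 5, calibration_bias = 1,
         noise_sigma0 = 0, noise_reference = 5000, seed = 1L,
         spacing = c(2, 2, 2), supersampling = 4L, nuclide = "F-18",
         acquisition_start = as.POSIXct("2026-01-01 10:00:00", tz = "UTC"))
  } else {
    list(phantom = builtin_phantom("iq_nema"), bkg_conc_kbq_ml = 2,
         contrast = 8, psf_fwhm_mm = 5, calibration_bias = 1,
         noise_sigma0 = 0, noise_reference = 5000, seed = 1L,
         spacing = c(2, 2, 2), supersampling = 4L, nuclide = "F-18",
         acquisition_start = as.POSIXct("2026-01-01 10:00:00", tz = "UTC"))
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown overrides: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  p <- utils::modifyList(defaults, overrides)
  spec <- p$phantom
  sphere_conc <- if (is.na(p$contrast)) 0 else p$bkg_conc_kbq_ml * p$contrast

  truth <- rasterize_phantom(spec, p$bkg_conc_kbq_ml, sphere_conc,
                             spacing = p$spacing,
                             supersampling = p$supersampling,
                             acquisition_start = p$acquisition_start,
                             nuclide = p$nuclide)
  cfg <- simulation_config(psf_fwhm_mm = p$psf_fwhm_mm,
                           noise_sigma0 = p$noise_sigma0,
                           noise_reference = p$noise_reference,
                           calibration_bias = p$calibration_bias,
                           seed = p$seed, supersampling = p$supersampling)
  scan <- simulate_scan(truth, cfg)

  fills <- list(
    background = .fill_for_concentration(p$bkg_conc_kbq_ml,
                                         spec$body_volume_l * 1000, p$nuclide,
                                         p$acquisition_start, "background"))
  if (sphere_conc > 0) {
    fills$sphere_stock <- .fill_for_concentration(sphere_conc, 1000, p$nuclide,
                                                  p$acquisition_start,
                                                  "sphere_stock")
  }
  manifest <- list(fixture = name, phantom = spec$name,
                   radionuclide = p$nuclide,
                   bkg_conc_kbq_ml = p$bkg_conc_kbq_ml,
                   sphere_conc_kbq_ml = sphere_conc,
                   contrast = if (is.na(p$contrast)) NULL else p$contrast,
                   injected_bias = p$calibration_bias,
                   psf_fwhm_mm = p$psf_fwhm_mm,
                   noise_sigma0 = p$noise_sigma0,
                   noise_reference = p$noise_reference, seed = p$seed,
                   spacing_mm = p$spacing, supersampling = p$supersampling,
                   acquisition_start = format(p$acquisition_start,
                                              "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  out <- list(truth = truth, scan = scan, fills = fills, spec = spec,
              manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(truth, file.path(dir, "truth.nii.gz"))
    write_volume(scan, file.path(dir, "scan.nii.gz"))
    write_fill_json(fills, file.path(dir, "fills.json"))
    write_phantom_json(spec, file.path(dir, "phantom.json"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
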